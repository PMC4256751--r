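# ptmgraft

Graft post-translational modifications (PTMs) onto existing 3D protein and
peptide structures.

Many disease-relevant protein modifications — nitration of tyrosines under
nitrosative stress, malondialdehyde–acetaldehyde (MAA) adducts on lysines
after lipid peroxidation, citrullination of arginines in rheumatoid
arthritis, oxidation of methionines and cysteines — are rarely present in
deposited crystal structures. Researchers who want to ask *"would this
modification fit? what would it clash with? which residues are even
reachable?"* need a way to introduce the modified side chain into an
existing model quickly and reproducibly. `ptmgraft` does exactly that for
ten common PTM classes, working directly on PDB files, for structural
biologists and immunologists exploring modified epitopes, enzyme
inhibition or surface adduction before committing to experiments.

## What it computes

* **Atom placement** — new atoms are positioned from internal coordinates
  (bond length r, bond angle θ, torsion φ) by the natural extension
  reference frame (NeRF) construction: given reference positions a, b, c,
  the new atom d satisfies |d−c| = r, ∠(b,c,d) = θ and φ(a,b,c,d) = φ.
* **Surface pre-selection** — per-atom solvent-accessible surface area
  (SASA) by the Shrake–Rupley method: the fraction of quasi-uniform points
  on the sphere of radius r_vdw + r_probe not occluded by any neighbor,
  times 4π(r_vdw + r_probe)². Bondi radii, water probe 1.4 Å. A cutoff in
  Å² on the target atom (e.g. Lys NZ ≥ 25 Å²) restricts modification to
  exposed sites.
* **Stereochemistry** — R/S labels at sulfoxide, sulfinyl and carbon
  stereocenters are assigned from the signed volume of the CIP-priority-
  ordered substituent tetrahedron; diastereomeric variants (Met-sulfoxide
  R/S, Cys-S-dioxide R/S, FAAB R/S, hydroxyproline 4R/4S) are built to
  their declared configuration.
* **Strain relief** — local van-der-Waals strain Σ max(0, r_i + r_j − d)²
  over non-bonded pairs near the modified residue, minimized by an
  exhaustive grid scan over its side-chain and adduct torsions
  (optimization levels 1–4 trade scan depth for resolution).

The ten classes: acetylation, carbamylation, citrullination, cysteine
oxidation, malondialdehyde adducts (MAA default), methionine oxidation,
methylation, nitration, proline hydroxylation, phosphorylation. Modified
residues are renamed to standard component codes where they exist (ALY,
CIR, CSO/CSD/OCS, SME, MLZ/MLY/M3L, NIY, HYP, SEP/TPO/PTR) and written as
HETATM with REMARK 999 provenance.

## Worked example

```r
library(ptmgraft)

pep <- build_peptide("KYKCK")          # ideal-geometry fixture peptide
res <- modify_structure(pep, modification_options("mda_adduct",
                                                  optimization_level = 2))
res$report
```

prints

```
<modification_report> 3 candidate(s): 3 modified, 0 skipped; total charge delta -3
 chain resi resn_before resn_after      mode  outcome n_added charge_delta
     A    1         LYS        MM1 sidechain modified      10           -1
     A    3         LYS        MM1 sidechain modified      10           -1
     A    5         LYS        MM1 sidechain modified      10           -1
 strain_before strain_after stereo
        0.4961        0.000
        4.5748        2.615
        4.5748        2.615
```

Each of the three lysines gained the 10-heavy-atom MAA
(4-methyl-dihydropyridine-dicarbaldehyde) ring on its epsilon amine,
eliminating one positive charge each (total −3); the torsion grid scan
reduced the local vdW overlap score (Å², quadratic overlap units) of every
adduct, e.g. 4.57 → 2.62 for Lys3. `write_pdb(res$structure, "out.pdb")` then
produces a PDB with `MM1` HETATM residues and provenance REMARKs.

The command line covers the same pipeline:

```sh
Rscript inst/scripts/ptmgraft --in model.pdb --ptm nitration --out model_niy.pdb
Rscript inst/scripts/ptmgraft --list-ptms
Rscript inst/scripts/ptmgraft --in model.pdb --clashes-only --clash-report bumps.tsv
```

Useful flags: `--variant`, `--select "chain A and resi 1-120"`,
`--surface-cutoff 25`, `--optimize 3`, `--probe-baseline`, `--n-termini`,
`--position 1|2` (nitration ortho position).

## Layout

* `R/` — structure I/O and selection, geometry core, PTM catalog accessors,
  SASA, strain/optimizer, engine, CLI, fixture builders.
* `inst/extdata/ptm_catalog.json` — the versioned, human-readable catalog
  (one record per variant) that chemists can extend without code changes.
* `vignettes/ptm-grafting.Rmd` — the methods vignette: model, assumptions,
  parameter choices, limitations.
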