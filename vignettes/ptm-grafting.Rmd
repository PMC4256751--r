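---
title: "Grafting post-translational modifications: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grafting post-translational modifications: models, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmgraft)
```

## The problem and the approach

Deposited protein structures almost never carry the pathophysiological
modifications — nitrotyrosine, malondialdehyde–acetaldehyde (MAA) adducts,
citrulline, methionine sulfoxide — that experiments implicate. `ptmgraft`
edits an existing model instead of predicting one: it finds the residues a
modification chemically targets, grafts the new atoms at ideal internal
coordinates, renames the residue to its standard component code, and
relieves the worst steric consequences by rotating the modified side chain.
This is deliberately *local* modeling: the backbone and all other residues
stay fixed. The product is a hypothesis-generation model, not a refined
structure.

The pipeline for every class is the same: **candidate discovery**
(target residue names ∩ user selection, minus residues already modified,
minus buried targets if a surface cutoff is set) → **sequential grafting**
→ **renaming and provenance** → **optional strain minimization** →
**report**.

## Atom placement

New atoms are placed by the natural extension reference frame (NeRF)
construction from three reference positions plus (bond length, bond angle,
torsion). NeRF is the standard, numerically stable choice for
internal-to-Cartesian conversion; the round trip through the package's
torsion measurement is exact to well below 1e-6 (length in Å, angles in
degrees), which the test suite asserts over 10,000 randomized inputs. All
interfaces speak degrees; radians exist only internally.

Each recipe in the catalog (`inst/extdata/ptm_catalog.json`, one record per
variant) lists its added atoms in build order with references that may name
anchor atoms (`@A`,`@B`,`@C` — a bonded chain ending at the target atom) or
previously built atoms. Geometry values are chemical-component-dictionary-
like ideal values: amide C–N 1.34–1.36 Å, C=O 1.22–1.23 Å, aromatic ring
1.38–1.39 Å, P–O ester 1.60 / phosphate 1.52 Å, tetrahedral 109.5°,
trigonal 120°. Two deliberate simplifications: the MAA dihydropyridine ring
is built as a planar regular hexagon (its C4 is chemically sp³; the ~10°
pucker is below the resolution of a clash screen), and ring closures
(hexagon C6–N1) are exact by construction rather than optimized.

## Stereochemistry

R/S labels are computed from the signed volume of the tetrahedron spanned
by the four substituents ordered by descending CIP priority: with the
lowest-priority substituent pointing away, a clockwise 1→2→3 arrangement is
R, which corresponds to a *negative* signed volume
`det[n1−n4, n2−n4, n3−n4]`. The sign convention was pinned once against an
independent cheminformatics CIP implementation on constructed test
molecules, and the mirror-flip property (a reflection always inverts the
label) is tested unconditionally. Sulfoxide and sulfinyl sulfurs carry a
lone pair in the fourth position; it is represented by a virtual point
opposite the vector sum of the three real substituents, and the same
virtual-point rule serves for the implicit hydrogen at carbon centers in
heavy-atom-only models.

CIP priorities are *catalog data*, not computed: the package ships an
ordered substituent list per stereocenter (six stereocenters exist in the
whole catalog), because a general CIP engine would be far more code than
the problem warrants. Likewise, the per-variant torsions that realize R
versus S were calibrated once during development against the chirality
checker and frozen in the catalog file.

For methionine oxidation the literature-facing variants are `R`, `S` and
`racemic-choice` (the default). A racemic pick cannot be random in a
deterministic tool, so `racemic-choice` builds both isomers and keeps the
one with lower local strain, with ties going to R. The nitration default
resolves its choice — which of the two equivalent ortho ring carbons
receives the nitro group — the same way, with ties going to the
lexicographically lower ring-carbon name; `position = 1|2` overrides it.

## Solvent accessibility

Per-atom SASA uses Shrake–Rupley with a deterministic Fibonacci sphere
lattice (no RNG anywhere in the package). Defaults: probe 1.4 Å (water),
960 points per atom (isolated-sphere error well under 1%), Bondi radii
(C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å; unknown elements 1.80 Å with a
warning). Hydrogens, waters and — by default — non-water HETATM ligands are
excluded from both the test set and the occlusion set, modeling the
unliganded solvent-exposed state; every atom still receives a (possibly
zero) entry. The cutoff applies to the *target atom* of the modification
(e.g. the lysine NZ), not to whole-residue relative accessibility, matching
how surface-restricted adduction is specified in the field. SASA is
computed once on the pre-modification structure, so candidate outcomes do
not depend on the order in which adducts accumulate.

A practical note on the cage fixtures used in testing: per-atom
Shrake–Rupley occlusion is local (an occluder matters only within the sum
of expanded radii, ≈ 6 Å for carbons), so a thin distant shell does *not*
bury an atom — the test cages are built snug (shell radius ≈ extent + 3 Å).

## Van-der-Waals strain and its minimization

Strain is the quadratic overlap penalty Σ max(0, r_i + r_j − d)² over pairs
of a moving set (the modified residue's side chain + adduct) against heavy
atoms within an 8 Å neighborhood, plus intra-moving pairs at graph distance
≥ 4 bonds. 1-2, 1-3 and 1-4 bonded pairs are excluded outright — this is a
coarse clash screen, not a force field, and penalizing normal rotamer
geometry would drown the signal. The quadratic form ranks a single deep
interpenetration above several grazing contacts, which is the ranking a
human inspecting clash discs would apply. Absolute values are therefore
meaningful only for ordering and zero/nonzero distinctions.

Minimization is an exhaustive grid scan over the residue's rotatable
torsions (non-ring, side-chain/adduct bonds ordered proximal→distal):

| level | torsions scanned | step |
|------:|------------------|-----:|
| 1 | most distal only | 30° |
| 2 | two most distal | 30° |
| 3 | up to four | 20° |
| 4 | up to four | 10° |

The initial pose is always a grid member, so reported strain never
increases; ties are broken by the smallest total angular displacement from
the input pose. The scan is exact (it equals a brute-force enumeration,
which the tests assert on 1- and 2-torsion fixtures) but implemented
incrementally: a pair's distance is final after the deepest torsion moving
exactly one of its endpoints, allowing per-level partial sums and
branch-and-bound pruning without changing the result. `probe_baseline`
implements the shortcut of skipping the scan when the graft added no strain
beyond the residue's pre-modification baseline + ε, with ε = 0.01 Å²
(comfortably below any meaningful overlap: a 0.1 Å contact scores
0.01 Å²).

## Candidate filtering rules

Residues already bearing a product code or a PTM tag are skipped
(`skipped_already_modified`), which makes every run idempotent. Cysteines
whose SG lies within 2.3 Å of another SG are treated as disulfides and are
not oxidation candidates. Incomplete side chains are skipped
(`skipped_missing_atoms`), never rebuilt. N-terminal capping (acetylation,
carbamylation, methylation, MDA adducts) applies to the backbone N of each
chain-initial residue except proline, keeps the residue name and records
the event in the PTM tag and REMARKs. One consequence of the
skip-if-tagged rule is that v1 supports a single modification per residue;
stacking (e.g. a nitrated *and* phosphorylated tyrosine) would require
relaxing the filter to track target-atom availability instead.

## What the synthetic fixtures do and do not establish

`build_peptide` produces ideal-geometry peptides (N–CA 1.458, CA–C 1.525,
C–N 1.329 Å; helix −57/−47, extended −140/135; all-anti side-chain χ,
except aromatic χ² at 75° where the planar-eclipsed value would
manufacture a spurious backbone contact) and `build_cage` produces
occluding shells; both are deterministic. Green tests on these fixtures
establish the *mechanics* — placement accuracy, stereochemical control,
filter logic, optimizer exactness — on clean inputs. They do not establish
robustness to real-structure pathology (alternate conformations beyond
highest-occupancy selection, missing atoms beyond the skip rule, unusual
protonation) nor the biological plausibility of any particular adduct
geometry, and the strain score's absolute scale is not comparable across
radius sets or to any other program's sculpting energy.

## Numerical choices and degenerate inputs

Collinear NeRF references, zero-length rotation axes, coincident or planar
stereocenter substituents all raise errors rather than returning garbage.
Torsion comparisons are made modulo 360°; grid ties at 1e-9 resolution fall
back to the displacement rule. PDB coordinates are written at the format's
8.3 fixed precision, so a write/read round trip preserves coordinates to
0.001 Å and is byte-stable from the second write onward. Altlocs keep the
highest-occupancy conformer (modification is single-conformer modeling);
residue numbering and insertion codes pass through verbatim.

## Known limitations

* Local relief only: no backbone motion, no neighbor repacking, no global
  conformational response — exactly the regime where modification-induced
  rearrangements would be largest.
* Formal charge deltas are bookkeeping (dianionic phosphate assumed; no
  pKa logic); no force-field or electrostatics output.
* Nitration targets tyrosine only; the MDA variant set is the minimal
  chemically distinct trio (MAA ring, FAAB with R/S, N-propenal).
* mmCIF, multi-conformer ensembles and crystallographic symmetry are out
  of scope; one model of a multi-model file is used.
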