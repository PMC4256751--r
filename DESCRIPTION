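Package: ptmgraft
Title: Graft Post-Translational Modifications onto Protein Structures
Version: 1.0.0
Authors@R:
    person("Sam", "Ridley", email = "sam.ridley@example.org",
           role = c("aut", "cre"))
Description: Introduces common post-translational modifications (PTMs) into
    existing 3D protein or peptide structures in PDB format. Ten modification
    classes are supported (acetylation, carbamylation, citrullination,
    cysteine oxidation, malondialdehyde adducts, methionine oxidation,
    methylation, nitration, proline hydroxylation and phosphorylation), with
    per-atom solvent-accessible surface area pre-selection of exposed target
    atoms (Shrake-Rupley), control over stereochemical variants (R/S
    diastereomers at sulfoxide, sulfinyl and carbon centers), and local
    van-der-Waals strain minimization of the modified residue by torsion-grid
    scanning. Atoms are placed from internal coordinates by the natural
    extension reference frame (NeRF) construction; modified residues are
    renamed to standard component codes where these exist and written back as
    annotated PDB with a machine-readable modification report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
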