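# Bundled chemical data: Bondi van-der-Waals radii, amino-acid codes,
# ideal-geometry side-chain construction tables and intra-residue bond
# templates for the 20 standard residues. Geometry follows standard
# stereochemistry tables (Engh & Huber-like values, rounded); side-chain
# chi angles default to all-anti (180 deg) except where a branch or ring
# dictates otherwise.

# Bondi (1964) radii; unknown elements fall back to 1.80 A with a warning.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
                F = 1.47, CL = 1.75, BR = 1.85, SE = 1.90)
.VDW_DEFAULT <- 1.80

.vdw_radius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  if (anyNA(r)) {
    bad <- unique(toupper(element)[is.na(r)])
    warning("unknown element(s) ", paste(bad, collapse = ", "),
            "; using default vdW radius ", .VDW_DEFAULT, " A", call. = FALSE)
    r[is.na(r)] <- .VDW_DEFAULT
  }
  unname(r)
}

.AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

.WATER_RESN <- c("HOH", "WAT", "DOD")

# Backbone ideal values used by the peptide builder.
.BB <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.5, omega = 180
)

# Improper torsion C-N-CA-CB realizing the L (2S) alpha carbon
# (calibrated once against assign_chirality; see tests).
.CB_IMPROPER <- -122.6

# Side-chain construction: one row per heavy atom, placed in order by NeRF.
# refs = (a, b, c): the new atom bonds c; dihedral is a-b-c-new in degrees.
.sc_row <- function(name, el, a, b, c, L, th, ph)
  list(name = name, element = el, refs = c(a, b, c),
       length = L, angle = th, dihedral = ph)

.SIDE_CHAINS <- list(
  ALA = list(),
  ARG = list(
    .sc_row("CG",  "C", "N",  "CA", "CB", 1.52, 114, 180),
    .sc_row("CD",  "C", "CA", "CB", "CG", 1.52, 111, 180),
    .sc_row("NE",  "N", "CB", "CG", "CD", 1.46, 112, 180),
    .sc_row("CZ",  "C", "CG", "CD", "NE", 1.33, 124, 180),
    .sc_row("NH1", "N", "CD", "NE", "CZ", 1.33, 120, 0),
    .sc_row("NH2", "N", "CD", "NE", "CZ", 1.33, 120, 180)),
  ASN = list(
    .sc_row("CG",  "C", "N",  "CA", "CB", 1.52, 113, 180),
    .sc_row("OD1", "O", "CA", "CB", "CG", 1.23, 121, 0),
    .sc_row("ND2", "N", "CA", "CB", "CG", 1.33, 117, 180)),
  ASP = list(
    .sc_row("CG",  "C", "N",  "CA", "CB", 1.52, 113, 180),
    .sc_row("OD1", "O", "CA", "CB", "CG", 1.25, 118, 0),
    .sc_row("OD2", "O", "CA", "CB", "CG", 1.25, 118, 180)),
  CYS = list(
    .sc_row("SG", "S", "N", "CA", "CB", 1.81, 114, 180)),
  GLN = list(
    .sc_row("CG",  "C", "N",  "CA", "CB", 1.52, 114, 180),
    .sc_row("CD",  "C", "CA", "CB", "CG", 1.52, 111, 180),
    .sc_row("OE1", "O", "CB", "CG", "CD", 1.23, 121, 0),
    .sc_row("NE2", "N", "CB", "CG", "CD", 1.33, 117, 180)),
  GLU = list(
    .sc_row("CG",  "C", "N",  "CA", "CB", 1.52, 114, 180),
    .sc_row("CD",  "C", "CA", "CB", "CG", 1.52, 111, 180),
    .sc_row("OE1", "O", "CB", "CG", "CD", 1.25, 118, 0),
    .sc_row("OE2", "O", "CB", "CG", "CD", 1.25, 118, 180)),
  GLY = list(),
  HIS = list(
    .sc_row("CG",  "C", "N",  "CA", "CB",  1.50, 114, 180),
    .sc_row("ND1", "N", "CA", "CB", "CG",  1.38, 122, 90),
    .sc_row("CD2", "C", "CA", "CB", "CG",  1.36, 129, -90),
    .sc_row("CE1", "C", "CB", "CG", "ND1", 1.32, 109, 180),
    .sc_row("NE2", "N", "CG", "ND1", "CE1", 1.32, 108, 0)),
  ILE = list(
    .sc_row("CG1", "C", "N",  "CA", "CB",  1.53, 110, 180),
    .sc_row("CG2", "C", "N",  "CA", "CB",  1.53, 110, 60),
    .sc_row("CD1", "C", "CA", "CB", "CG1", 1.53, 113, 180)),
  LEU = list(
    .sc_row("CG",  "C", "N",  "CA", "CB", 1.53, 116, 180),
    .sc_row("CD1", "C", "CA", "CB", "CG", 1.53, 110, 180),
    .sc_row("CD2", "C", "CA", "CB", "CG", 1.53, 110, 60)),
  LYS = list(
    .sc_row("CG", "C", "N",  "CA", "CB", 1.52, 114, 180),
    .sc_row("CD", "C", "CA", "CB", "CG", 1.52, 111, 180),
    .sc_row("CE", "C", "CB", "CG", "CD", 1.52, 111, 180),
    .sc_row("NZ", "N", "CG", "CD", "CE", 1.47, 112, 180)),
  MET = list(
    .sc_row("CG", "C", "N",  "CA", "CB", 1.52, 114, 180),
    .sc_row("SD", "S", "CA", "CB", "CG", 1.80, 112, 180),
    .sc_row("CE", "C", "CB", "CG", "SD", 1.79, 100, 180)),
  PHE = list(
    .sc_row("CG",  "C", "N",  "CA", "CB",  1.51, 114, 180),
    .sc_row("CD1", "C", "CA", "CB", "CG",  1.39, 120, 75),
    .sc_row("CD2", "C", "CA", "CB", "CG",  1.39, 120, -105),
    .sc_row("CE1", "C", "CB", "CG", "CD1", 1.39, 120, 180),
    .sc_row("CE2", "C", "CB", "CG", "CD2", 1.39, 120, 180),
    .sc_row("CZ",  "C", "CG", "CD1", "CE1", 1.39, 120, 0)),
  PRO = list(
    .sc_row("CG", "C", "N",  "CA", "CB", 1.50, 105, 20),
    .sc_row("CD", "C", "CA", "CB", "CG", 1.51, 105, -30)),
  SER = list(
    .sc_row("OG", "O", "N", "CA", "CB", 1.42, 111, 180)),
  THR = list(
    .sc_row("OG1", "O", "N", "CA", "CB", 1.43, 110, 180),
    .sc_row("CG2", "C", "N", "CA", "CB", 1.52, 110, -60)),
  TRP = list(
    .sc_row("CG",  "C", "N",  "CA",  "CB",  1.50, 114, 180),
    .sc_row("CD1", "C", "CA", "CB",  "CG",  1.37, 127, 90),
    .sc_row("CD2", "C", "CA", "CB",  "CG",  1.43, 126, -90),
    .sc_row("NE1", "N", "CB", "CG",  "CD1", 1.38, 110, 180),
    .sc_row("CE2", "C", "CB", "CG",  "CD2", 1.41, 107, 180),
    .sc_row("CE3", "C", "CB", "CG",  "CD2", 1.40, 133, 0),
    .sc_row("CZ2", "C", "CG", "CD2", "CE2", 1.40, 122, 180),
    .sc_row("CZ3", "C", "CG", "CD2", "CE3", 1.39, 118, 180),
    .sc_row("CH2", "C", "CD2", "CE2", "CZ2", 1.37, 117, 0)),
  TYR = list(
    .sc_row("CG",  "C", "N",  "CA", "CB",  1.51, 114, 180),
    .sc_row("CD1", "C", "CA", "CB", "CG",  1.39, 120, 75),
    .sc_row("CD2", "C", "CA", "CB", "CG",  1.39, 120, -105),
    .sc_row("CE1", "C", "CB", "CG", "CD1", 1.39, 120, 180),
    .sc_row("CE2", "C", "CB", "CG", "CD2", 1.39, 120, 180),
    .sc_row("CZ",  "C", "CG", "CD1", "CE1", 1.39, 120, 0),
    .sc_row("OH",  "O", "CD1", "CE1", "CZ", 1.38, 120, 180)),
  VAL = list(
    .sc_row("CG1", "C", "N", "CA", "CB", 1.53, 110, 180),
    .sc_row("CG2", "C", "N", "CA", "CB", 1.53, 110, -60))
)

# Intra-residue heavy-atom bond templates (side chain; backbone N-CA, CA-C,
# C-O and C-OXT are added generically). Proline's CD-N ring closure included.
.SC_BONDS <- list(
  ALA = list(c("CA", "CB")),
  ARG = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","NE"),
             c("NE","CZ"), c("CZ","NH1"), c("CZ","NH2")),
  ASN = list(c("CA","CB"), c("CB","CG"), c("CG","OD1"), c("CG","ND2")),
  ASP = list(c("CA","CB"), c("CB","CG"), c("CG","OD1"), c("CG","OD2")),
  CYS = list(c("CA","CB"), c("CB","SG")),
  GLN = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","OE1"),
             c("CD","NE2")),
  GLU = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","OE1"),
             c("CD","OE2")),
  GLY = list(),
  HIS = list(c("CA","CB"), c("CB","CG"), c("CG","ND1"), c("CG","CD2"),
             c("ND1","CE1"), c("CE1","NE2"), c("NE2","CD2")),
  ILE = list(c("CA","CB"), c("CB","CG1"), c("CB","CG2"), c("CG1","CD1")),
  LEU = list(c("CA","CB"), c("CB","CG"), c("CG","CD1"), c("CG","CD2")),
  LYS = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","CE"),
             c("CE","NZ")),
  MET = list(c("CA","CB"), c("CB","CG"), c("CG","SD"), c("SD","CE")),
  PHE = list(c("CA","CB"), c("CB","CG"), c("CG","CD1"), c("CG","CD2"),
             c("CD1","CE1"), c("CD2","CE2"), c("CE1","CZ"), c("CE2","CZ")),
  PRO = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","N")),
  SER = list(c("CA","CB"), c("CB","OG")),
  THR = list(c("CA","CB"), c("CB","OG1"), c("CB","CG2")),
  TRP = list(c("CA","CB"), c("CB","CG"), c("CG","CD1"), c("CG","CD2"),
             c("CD1","NE1"), c("NE1","CE2"), c("CD2","CE2"), c("CD2","CE3"),
             c("CE2","CZ2"), c("CE3","CZ3"), c("CZ2","CH2"), c("CZ3","CH2")),
  TYR = list(c("CA","CB"), c("CB","CG"), c("CG","CD1"), c("CG","CD2"),
             c("CD1","CE1"), c("CD2","CE2"), c("CE1","CZ"), c("CE2","CZ"),
             c("CZ","OH")),
  VAL = list(c("CA","CB"), c("CB","CG1"), c("CB","CG2"))
)
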