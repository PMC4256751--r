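# Shared fixture builders. Everything is generated in code; no data files.

# A single extra occluder atom (chain X) at an explicit position.
wall_atom <- function(pos, element = "C") {
  new_structure(data.frame(
    serial = 1L, name = element, altloc = "", resn = "CAG", chain = "X",
    resi = 1L, ins = "", x = pos[1], y = pos[2], z = pos[3], occ = 1, b = 0,
    element = element, hetatm = FALSE, ptm_tag = "", stringsAsFactors = FALSE))
}

# n free-standing carbon pseudo-atoms at given coordinate matrix.
atom_cluster <- function(P, element = "C") {
  n <- nrow(P)
  new_structure(data.frame(
    serial = seq_len(n), name = element, altloc = "", resn = "CAG",
    chain = "A", resi = seq_len(n), ins = "", x = P[, 1], y = P[, 2],
    z = P[, 3], occ = 1, b = 0, element = element, hetatm = FALSE,
    ptm_tag = "", stringsAsFactors = FALSE))
}

res_key_of <- function(s, chain, resi) paste(chain, resi, "", sep = "|")

res_atom_xyz <- function(s, key, name) {
  at <- s$atoms
  i <- which(paste(at$chain, at$resi, at$ins, sep = "|") == key &
               at$name == name)
  stopifnot(length(i) == 1)
  c(at$x[i], at$y[i], at$z[i])
}

res_serials <- function(s, key) {
  at <- s$atoms
  at$serial[paste(at$chain, at$resi, at$ins, sep = "|") == key]
}

# Tyr pocket fixture: AYA peptide plus one occluder placed exactly where an
# ortho nitro group would go (in-plane, 3.45 A from CE1), so the native
# structure is clash-free but nitration at position 1 clashes.
tyr_pocket <- function() {
  y <- build_peptide("AYA")
  key <- res_key_of(y, "A", 2)
  wall <- place_atom(res_atom_xyz(y, key, "OH"), res_atom_xyz(y, key, "CZ"),
                     res_atom_xyz(y, key, "CE1"), 3.45, 120, 0)
  combine_structures(y, wall_atom(wall))
}

# Lysine + MAA ring pressed against a wall: a compact optimizer test case.
maa_wall <- function() {
  s <- build_peptide("KA")
  key <- res_key_of(s, "A", 1)
  res <- apply_ptm(s, key, get_definition("mda_adduct", "MAA"),
                   modification_options("mda_adduct"))
  ring <- res$structure$atoms[res$structure$atoms$name == "C4", ]
  list(structure = combine_structures(
         res$structure, wall_atom(c(ring$x + 1.2, ring$y, ring$z))),
       key = key)
}

# Rigid motion: random rotation + translation applied to a coordinate matrix.
random_rigid <- function(P, seed) {
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  t(R %*% t(P)) + matrix(stats::rnorm(3, sd = 5), nrow(P), 3, byrow = TRUE)
}

# Brute-force torsion grid oracle: scans the most distal `n_t` torsions at
# `step` degrees with rotate_about_bond + vdw_strain, returns the minimum.
grid_oracle <- function(s, key, n_t, step) {
  tors <- utils::tail(ptmgraft:::.residue_torsions(s, key), n_t)
  mov <- ptmgraft:::.residue_moving_set(s, key)
  offsets <- seq(0, 360 - step, by = step)
  grid <- do.call(expand.grid, rep(list(offsets), length(tors)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    st <- s
    for (d in seq_along(tors)) {
      o <- grid[r, d]
      if (o != 0)
        st <- rotate_about_bond(st, tors[[d]]$tail, tors[[d]]$head,
                                tors[[d]]$moving, o)
    }
    best <- min(best, vdw_strain(st, mov)$value)
  }
  best
}

# Rigid translation of a whole structure (bonds are unaffected).
shift_structure <- function(s, d) {
  s$atoms$x <- s$atoms$x + d[1]
  s$atoms$y <- s$atoms$y + d[2]
  s$atoms$z <- s$atoms$z + d[3]
  s
}
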