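# Programmatic test structures: ideal-geometry peptides and occluding cages.
# Everything here is deterministic (no RNG).

#' Build an ideal-geometry peptide
#'
#' Constructs an all-heavy-atom peptide from ideal internal coordinates
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 A, standard backbone angles, omega
#' fixed at 180). Side chains are placed at canonical rotamers (all-anti chi
#' angles except where rings or branches dictate otherwise).
#'
#' @param sequence One-letter amino-acid string (standard residues only).
#' @param conformation `"extended"` (phi/psi = -140/135), `"helix"`
#'   (-57/-47), or an n x 2 matrix of (phi, psi) in degrees.
#' @param chain Chain identifier (single character).
#' @return A `ptm_structure`.
#' @examples
#' pep <- build_peptide("AKA")
#' @export
build_peptide <- function(sequence, conformation = "extended", chain = "A") {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (!length(letters1)) stop("empty sequence", call. = FALSE)
  unknown <- setdiff(letters1, names(.AA1TO3))
  if (length(unknown))
    stop("unknown residue letter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  n <- length(letters1)
  phipsi <- if (is.matrix(conformation)) {
    stopifnot(nrow(conformation) == n, ncol(conformation) == 2)
    conformation
  } else if (identical(conformation, "helix")) {
    matrix(rep(c(-57, -47), each = n), n)
  } else if (identical(conformation, "extended")) {
    matrix(rep(c(-140, 135), each = n), n)
  } else stop("conformation must be 'helix', 'extended' or a phi/psi matrix",
              call. = FALSE)

  rows <- list()
  emit <- function(name, el, resi, resn, p)
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = 0L, name = name, altloc = "", resn = resn, chain = chain,
      resi = resi, ins = "", x = p[1], y = p[2], z = p[3], occ = 1, b = 0,
      element = el, hetatm = FALSE, ptm_tag = "", stringsAsFactors = FALSE)

  pos <- list()  # per-residue named coordinate lists
  for (i in seq_len(n)) {
    resn <- .AA1TO3[[letters1[i]]]
    p <- list()
    if (i == 1) {
      p$N <- c(0, 0, 0)
      p$CA <- c(.BB$n_ca, 0, 0)
      th <- .deg2rad(180 - .BB$ang_n_ca_c)
      p$C <- p$CA + .BB$ca_c * c(cos(th), sin(th), 0)
    } else {
      prev <- pos[[i - 1]]
      p$N <- place_atom(prev$N, prev$CA, prev$C, .BB$c_n, .BB$ang_ca_c_n,
                        phipsi[i - 1, 2])
      p$CA <- place_atom(prev$CA, prev$C, p$N, .BB$n_ca, .BB$ang_c_n_ca,
                         .BB$omega)
      p$C <- place_atom(prev$C, p$N, p$CA, .BB$ca_c, .BB$ang_n_ca_c,
                        phipsi[i, 1])
    }
    # carbonyl O anti to the next N (psi + 180)
    p$O <- place_atom(p$N, p$CA, p$C, .BB$c_o, .BB$ang_ca_c_o,
                      phipsi[i, 2] + 180)
    if (resn != "GLY")
      p$CB <- place_atom(p$C, p$N, p$CA, 1.53, 110.5, .CB_IMPROPER)
    for (sc in .SIDE_CHAINS[[resn]]) {
      refs <- lapply(sc$refs, function(nm) p[[nm]])
      if (any(vapply(refs, is.null, logical(1))))
        stop("internal: unresolved side-chain reference for ", resn,
             call. = FALSE)
      p[[sc$name]] <- place_atom(refs[[1]], refs[[2]], refs[[3]],
                                 sc$length, sc$angle, sc$dihedral)
    }
    pos[[i]] <- p
    order_names <- c("N", "CA", "C", "O",
                     setdiff(names(p), c("N", "CA", "C", "O")))
    for (nm in order_names) {
      el <- if (nm %in% c("N",  "NZ")) "N" else substr(gsub("[0-9]", "", nm), 1, 1)
      emit(nm, el, i, resn, p[[nm]])
    }
  }
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  new_structure(at, source = sprintf("build_peptide(%s)", sequence))
}

#' Surround a structure with an occluding shell of pseudo-atoms
#'
#' Places `n_shell` carbon pseudo-atoms on a Fibonacci sphere of radius
#' `shell_radius` around the centroid of `center_atoms`, so that interior
#' atoms lose essentially all solvent accessibility. The shell is appended
#' as residue `CAG` on chain `X` (ATOM records, so it participates in
#' occlusion).
#'
#' @param center_atoms A `ptm_structure` to enclose.
#' @param shell_radius Sphere radius in Angstrom; must exceed the maximal
#'   extent of the enclosed atoms by at least 3 A.
#' @param n_shell Number of shell atoms (0 leaves the structure unchanged).
#' @return The combined `ptm_structure`.
#' @export
build_cage <- function(center_atoms, shell_radius, n_shell) {
  at <- center_atoms$atoms
  ctr <- c(mean(at$x), mean(at$y), mean(at$z))
  ext <- max(sqrt((at$x - ctr[1])^2 + (at$y - ctr[2])^2 + (at$z - ctr[3])^2))
  if (shell_radius <= ext + 3)
    stop("shell_radius too small: needs > max extent + 3 A (",
         round(ext + 3, 2), ")", call. = FALSE)
  if (n_shell == 0) return(center_atoms)
  pts <- .fibonacci_sphere(n_shell)
  shell <- data.frame(
    serial = 0L, name = "C", altloc = "", resn = "CAG", chain = "X",
    resi = seq_len(n_shell), ins = "",
    x = ctr[1] + shell_radius * pts[, 1],
    y = ctr[2] + shell_radius * pts[, 2],
    z = ctr[3] + shell_radius * pts[, 3],
    occ = 1, b = 0, element = "C", hetatm = FALSE, ptm_tag = "",
    stringsAsFactors = FALSE)
  combined <- rbind(at, shell)
  combined$serial <- seq_len(nrow(combined))
  new_structure(combined, remarks = center_atoms$remarks,
                source = center_atoms$source)
}
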