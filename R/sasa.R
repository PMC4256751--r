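# Shrake-Rupley solvent-accessible surface area, per atom, with a
# deterministic Fibonacci sphere lattice (no randomness).

# Quasi-uniform unit sphere points (golden-angle lattice).
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (i - 0.5)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' For each heavy atom, the fraction of quasi-uniform test points on a sphere
#' of radius `r_vdw + probe` that fall inside no other atom's expanded
#' sphere, times the full sphere area. Bondi van-der-Waals radii are used
#' (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 A; unknown elements 1.80 A with a
#' warning). Hydrogens are excluded from both the test set and the occlusion
#' set and report an area of 0; waters and (by default) non-water HETATM
#' atoms are likewise excluded, modelling the unliganded solvent-exposed
#' state.
#'
#' @param s A `ptm_structure` with at least one heavy atom.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sphere test points per atom (default 960).
#' @param include_het Include non-water HETATM atoms in the calculation.
#' @return An object of class `sasa_result`: list with `area` (data frame
#'   `serial`, `area` in A^2, one row per structure atom), `probe`,
#'   `n_points`.
#' @export
compute_sasa <- function(s, probe = 1.4, n_points = 960, include_het = FALSE) {
  at <- s$atoms
  active <- at$element != "H" & !(at$resn %in% .WATER_RESN)
  if (!include_het) active <- active & !at$hetatm
  if (!any(active)) stop("no heavy atoms to compute SASA for", call. = FALSE)
  idx <- which(active)
  n <- length(idx)
  X <- cbind(at$x[idx], at$y[idx], at$z[idx])
  R <- .vdw_radius(at$element[idx]) + probe
  pts <- .fibonacci_sphere(n_points)
  area <- numeric(n)
  # spatial binning: cells of the maximal interaction distance
  cell <- 2 * max(R)
  cx <- floor(X[, 1] / cell); cy <- floor(X[, 2] / cell); cz <- floor(X[, 3] / cell)
  ckey <- paste(cx, cy, cz)
  cells <- split(seq_len(n), ckey)
  cell_of <- function(i, dx, dy, dz) paste(cx[i] + dx, cy[i] + dy, cz[i] + dz)
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  for (i in seq_len(n)) {
    cand <- unlist(cells[unique(cell_of(i, offsets$dx, offsets$dy, offsets$dz))],
                   use.names = FALSE)
    cand <- cand[cand != i]
    if (length(cand)) {
      dx <- X[cand, 1] - X[i, 1]
      dy <- X[cand, 2] - X[i, 2]
      dz <- X[cand, 3] - X[i, 3]
      d2 <- dx * dx + dy * dy + dz * dz
      nb <- cand[d2 < (R[i] + R[cand])^2 & d2 > 1e-12]
    } else nb <- integer(0)
    if (!length(nb)) {
      acc_frac <- 1
    } else {
      P <- sweep(pts * R[i], 2, X[i, ], `+`)  # n_points x 3
      free <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(free)) break
        dj <- (P[free, 1] - X[j, 1])^2 + (P[free, 2] - X[j, 2])^2 +
          (P[free, 3] - X[j, 3])^2
        free[free] <- dj >= R[j]^2
      }
      acc_frac <- mean(free)
    }
    area[i] <- acc_frac * 4 * pi * R[i]^2
  }
  full <- data.frame(serial = at$serial, area = 0)
  full$area[match(at$serial[idx], full$serial)] <- area
  structure(list(area = full, probe = probe, n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  nz <- x$area$area[x$area$area > 0]
  cat(sprintf("<sasa_result> %d atoms (%d with area > 0), probe %.2f A, %d points\n",
              nrow(x$area), length(nz), x$probe, x$n_points))
  if (length(nz))
    cat(sprintf("  area range %.2f - %.2f A^2\n", min(nz), max(nz)))
  invisible(x)
}

#' Filter target atoms by solvent accessibility
#'
#' Keeps exactly the target atoms whose per-atom area is at least `cutoff`
#' square Angstrom; a cutoff of 0 keeps all targets.
#'
#' @param sasa A `sasa_result` from [compute_sasa()].
#' @param targets Integer vector of atom serials.
#' @param cutoff Area cutoff in A^2 (>= 0).
#' @return The subset of `targets` with `area >= cutoff`, in input order.
#' @export
surface_filter <- function(sasa, targets, cutoff) {
  if (!inherits(sasa, "sasa_result")) stop("sasa must be a sasa_result",
                                           call. = FALSE)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || is.na(cutoff) || cutoff < 0)
    stop("cutoff must be a single non-negative number", call. = FALSE)
  i <- match(targets, sasa$area$serial)
  if (anyNA(i)) stop("target atom(s) missing from the SASA result",
                     call. = FALSE)
  targets[sasa$area$area[i] >= cutoff]
}
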