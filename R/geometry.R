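# Coordinate mathematics: internal-coordinate atom placement (NeRF), torsion
# measurement, rotations about bonds, and R/S chirality assignment.
# All user-facing angles are degrees; radians are internal only.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.vcross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.vnorm <- function(v) sqrt(sum(v * v))

.vunit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("degenerate geometry: zero-length vector", call. = FALSE)
  v / n
}

#' Euclidean distance between two points
#'
#' @param p,q Numeric 3-vectors (Angstrom).
#' @return Distance in Angstrom.
#' @export
measure_distance <- function(p, q) .vnorm(q - p)

#' Bond angle at the middle point
#'
#' Angle p1-p2-p3, i.e. between the vectors p2->p1 and p2->p3.
#'
#' @param p1,p2,p3 Numeric 3-vectors.
#' @return Angle in degrees in \[0, 180\].
#' @export
measure_angle <- function(p1, p2, p3) {
  u <- .vunit(p1 - p2)
  v <- .vunit(p3 - p2)
  .rad2deg(atan2(.vnorm(.vcross(u, v)), sum(u * v)))
}

#' Signed torsion angle of four points
#'
#' Standard atan2 construction. The sign convention is fixed so that an
#' eclipsed arrangement (p4 on the same side as p1) measures 0 degrees, and is
#' the inverse of [place_atom()]: placing an atom with dihedral phi and
#' re-measuring returns phi.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Torsion in degrees in \[-180, 180\].
#' @export
measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (.vnorm(b1) < 1e-12 || .vnorm(b2) < 1e-12 || .vnorm(b3) < 1e-12)
    stop("degenerate geometry: coincident consecutive points", call. = FALSE)
  n1 <- .vcross(b1, b2)
  n2 <- .vcross(b2, b3)
  if (.vnorm(n1) < 1e-10 || .vnorm(n2) < 1e-10)
    stop("degenerate geometry: collinear points in dihedral", call. = FALSE)
  m <- .vcross(n1, b2 / .vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m * n2)
  # sign flipped relative to the raw atan2 so that place_atom() round-trips
  -.rad2deg(atan2(y, x))
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Natural extension reference frame construction: returns the point d with
#' `|d - c| = bond_length`, `angle(b, c, d) = bond_angle` and
#' `dihedral(a, b, c, d) = dihedral`.
#'
#' @param a,b,c Reference positions (numeric 3-vectors); must not be collinear.
#' @param bond_length Bond length c-d in Angstrom.
#' @param bond_angle Angle b-c-d in degrees, in (0, 180).
#' @param dihedral Torsion a-b-c-d in degrees.
#' @return Numeric 3-vector: the placed position.
#' @examples
#' place_atom(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), 1, 90, 0)    # (1, 1, 0)
#' place_atom(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), 1, 90, 180)  # (1, -1, 0)
#' @export
place_atom <- function(a, b, c, bond_length, bond_angle, dihedral) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            length(a) == 3, length(b) == 3, length(c) == 3)
  if (!is.finite(bond_length) || bond_length <= 0)
    stop("bond_length must be positive", call. = FALSE)
  bc <- c - b
  ab <- b - a
  ncr <- .vcross(ab, bc)
  if (.vnorm(ncr) < 1e-10 * max(.vnorm(ab) * .vnorm(bc), 1e-12))
    stop("degenerate frame: reference atoms are collinear", call. = FALSE)
  u <- .vunit(bc)
  n <- .vunit(ncr)
  m <- .vcross(n, u)
  th <- .deg2rad(bond_angle)
  ph <- .deg2rad(dihedral)
  d_local <- bond_length * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + u * d_local[1] + m * d_local[2] + n * d_local[3]
}

# Rodrigues rotation of a coordinate matrix (n x 3) about a unit axis through
# the origin by `ang` radians.
.rotate_mat <- function(P, axis, ang) {
  k <- .vunit(axis)
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  P %*% t(R)
}

#' Rotate a set of atoms about a bond
#'
#' Rotates the given atoms by `angle` degrees about the axis from
#' `axis_tail` to `axis_head` (right-hand rule looking from tail to head).
#' All other atoms are untouched.
#'
#' @param s A `ptm_structure`.
#' @param axis_tail,axis_head Atom serial numbers defining the axis; distinct.
#' @param moving Integer vector of atom serials to move; must exclude the axis
#'   atoms.
#' @param angle Rotation angle in degrees.
#' @return The modified structure.
#' @export
rotate_about_bond <- function(s, axis_tail, axis_head, moving, angle) {
  at <- s$atoms
  it <- match(axis_tail, at$serial)
  ih <- match(axis_head, at$serial)
  if (is.na(it) || is.na(ih) || it == ih)
    stop("axis atoms must be two distinct atoms of the structure", call. = FALSE)
  if (any(c(axis_tail, axis_head) %in% moving))
    stop("moving set must exclude the axis atoms", call. = FALSE)
  p0 <- c(at$x[it], at$y[it], at$z[it])
  p1 <- c(at$x[ih], at$y[ih], at$z[ih])
  if (.vnorm(p1 - p0) < 1e-9) stop("zero-length rotation axis", call. = FALSE)
  im <- match(moving, at$serial)
  if (anyNA(im)) stop("unknown atom serial in moving set", call. = FALSE)
  P <- cbind(at$x[im], at$y[im], at$z[im])
  P <- sweep(P, 2, p0)
  P <- .rotate_mat(P, p1 - p0, .deg2rad(angle))
  P <- sweep(P, 2, p0, `+`)
  s$atoms$x[im] <- P[, 1]
  s$atoms$y[im] <- P[, 2]
  s$atoms$z[im] <- P[, 3]
  s
}

#' Assign R/S chirality from coordinates
#'
#' Neighbors must be supplied in descending CIP priority order. The label is
#' the sign of the volume of the tetrahedron spanned by the neighbors: with
#' the lowest-priority substituent pointing away from the viewer, a clockwise
#' 1->2->3 arrangement is R. In this orientation-based form, R corresponds to
#' a negative signed volume `det[n1-n4, n2-n4, n3-n4]` (verified against an
#' independent CIP assignment on constructed test molecules). A lone pair or
#' implicit hydrogen occupying the fourth position may be represented by a
#' virtual position opposite the vector sum of the three real substituents.
#'
#' @param center Numeric 3-vector, position of the stereocenter.
#' @param neighbors 4 x 3 numeric matrix, rows ordered by CIP priority
#'   (highest first).
#' @return `"R"` or `"S"`.
#' @export
assign_chirality <- function(center, neighbors) {
  neighbors <- as.matrix(neighbors)
  stopifnot(nrow(neighbors) == 4, ncol(neighbors) == 3)
  d <- stats::dist(rbind(center, neighbors))
  if (any(d < 1e-6))
    stop("coincident positions at stereocenter", call. = FALSE)
  v1 <- neighbors[1, ] - neighbors[4, ]
  v2 <- neighbors[2, ] - neighbors[4, ]
  v3 <- neighbors[3, ] - neighbors[4, ]
  vol <- sum(v1 * .vcross(v2, v3))
  if (abs(vol) < 1e-9)
    stop("degenerate (planar) arrangement at stereocenter", call. = FALSE)
  if (vol < 0) "R" else "S"
}

# Virtual fourth substituent for a lone pair / implicit hydrogen: unit vector
# opposite the sum of the real substituent directions, 1 A from the center.
.virtual_substituent <- function(center, real3) {
  dirs <- sweep(as.matrix(real3), 2, center)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  center - .vunit(colSums(dirs))
}
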