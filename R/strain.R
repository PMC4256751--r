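# Local van-der-Waals strain: quadratic overlap penalty
# sum over pairs of max(0, r_i + r_j - d)^2, with 1-2, 1-3 and 1-4 bonded
# pairs excluded and hydrogens ignored. Minimization is an exhaustive grid
# scan over side-chain/adduct torsions of the modified residue.

.BASELINE_EPS <- 0.01  # A^2; threshold for the baseline-probe shortcut

# Candidate clash pairs for a moving set: (moving x static-within-
# neighborhood) plus intra-moving pairs, minus pairs closer than 4 bonds.
# Returns list(i, j, rsum) of serial pairs.
.strain_pairs <- function(s, moving, neighborhood = 8.0) {
  at <- s$atoms
  heavy <- at$serial[at$element != "H"]
  moving <- intersect(moving, heavy)
  if (!length(moving)) return(list(i = integer(0), j = integer(0),
                                   rsum = numeric(0)))
  Pm <- .coords_of(s, moving)
  static <- setdiff(heavy, moving)
  keep <- logical(length(static))
  if (length(static)) {
    Ps <- .coords_of(s, static)
    for (k in seq_len(nrow(Pm))) {
      d2 <- (Ps[, 1] - Pm[k, 1])^2 + (Ps[, 2] - Pm[k, 2])^2 +
        (Ps[, 3] - Pm[k, 3])^2
      keep <- keep | d2 <= neighborhood^2
    }
  }
  static <- static[keep]
  adj <- .bond_adjacency(s)
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (m in moving) {
    excl <- .bonded_within(adj, m, 3L)
    cand <- setdiff(static, excl)
    pairs_i <- c(pairs_i, rep(m, length(cand)))
    pairs_j <- c(pairs_j, cand)
    # intra-moving, counted once, graph distance >= 4
    mm <- setdiff(moving[moving > m], excl)
    pairs_i <- c(pairs_i, rep(m, length(mm)))
    pairs_j <- c(pairs_j, mm)
  }
  ei <- s$atoms$element[match(pairs_i, s$atoms$serial)]
  ej <- s$atoms$element[match(pairs_j, s$atoms$serial)]
  list(i = pairs_i, j = pairs_j, rsum = .vdw_radius(ei) + .vdw_radius(ej))
}

.strain_from_pairs <- function(s, pairs) {
  if (!length(pairs$i))
    return(list(value = 0, n_clashes = 0L, overlaps = numeric(0),
                d = numeric(0)))
  Pi <- .coords_of(s, pairs$i)
  Pj <- .coords_of(s, pairs$j)
  d <- sqrt(rowSums((Pi - Pj)^2))
  ov <- pmax(0, pairs$rsum - d)
  list(value = sum(ov^2), n_clashes = sum(ov > 0), overlaps = ov, d = d)
}

#' Van-der-Waals strain of a moving set in its environment
#'
#' Scores every pair of a moving atom against non-moving heavy atoms within
#' `neighborhood` Angstrom (plus intra-moving pairs separated by at least 4
#' bonds) with the quadratic overlap penalty `max(0, r_i + r_j - d)^2`.
#' Pairs 1-2, 1-3 or 1-4 bonded are excluded; hydrogens are ignored.
#'
#' @param s A `ptm_structure`.
#' @param moving Non-empty integer vector of atom serials.
#' @param neighborhood Neighborhood radius in Angstrom (default 8.0).
#' @return List of class `strain_score` with `value` (A^2), `n_clashes`,
#'   `neighborhood`, and `clashes`: a data frame of overlapping pairs
#'   (`serial_i`, `serial_j`, `distance`, `overlap`, `severity`) sorted by
#'   decreasing severity.
#' @export
vdw_strain <- function(s, moving, neighborhood = 8.0) {
  if (!length(moving)) stop("moving set must be non-empty", call. = FALSE)
  pairs <- .strain_pairs(s, moving, neighborhood)
  res <- .strain_from_pairs(s, pairs)
  sel <- which(res$overlaps > 0)
  clashes <- data.frame(serial_i = pairs$i[sel], serial_j = pairs$j[sel],
                        distance = res$d[sel], overlap = res$overlaps[sel],
                        severity = res$overlaps[sel]^2)
  clashes <- clashes[order(-clashes$severity), ]
  rownames(clashes) <- NULL
  structure(list(value = res$value, n_clashes = res$n_clashes,
                 neighborhood = neighborhood, clashes = clashes),
            class = "strain_score")
}

#' @export
print.strain_score <- function(x, ...) {
  cat(sprintf("<strain_score> %.4f A^2 over %d clash(es) (neighborhood %.1f A)\n",
              x$value, x$n_clashes, x$neighborhood))
  invisible(x)
}

#' Enumerate steric clashes involving a selection
#'
#' Retrospective clash listing (the `show_bumps` analog): every overlapping
#' heavy-atom pair with at least one partner in the selection, with the same
#' bonded-pair exclusions as [vdw_strain()], sorted by decreasing severity.
#'
#' @param s A `ptm_structure`.
#' @param selection Non-empty integer vector of atom serials.
#' @param neighborhood Neighborhood radius in Angstrom.
#' @return Data frame of clash records (`serial_i`, `serial_j`, `distance`,
#'   `overlap`, `severity`), possibly with zero rows; annotated with atom
#'   names/residues in columns `desc_i`, `desc_j`.
#' @export
enumerate_clashes <- function(s, selection, neighborhood = 8.0) {
  if (!length(selection)) stop("selection must be non-empty", call. = FALSE)
  cl <- vdw_strain(s, selection, neighborhood)$clashes
  describe <- function(ser) {
    i <- match(ser, s$atoms$serial)
    sprintf("%s/%s%d%s/%s", s$atoms$chain[i], s$atoms$resn[i],
            s$atoms$resi[i], s$atoms$ins[i], s$atoms$name[i])
  }
  if (nrow(cl)) {
    cl$desc_i <- describe(cl$serial_i)
    cl$desc_j <- describe(cl$serial_j)
  } else {
    cl$desc_i <- character(0)
    cl$desc_j <- character(0)
  }
  cl
}

# ---- torsion discovery ------------------------------------------------------

# Rotatable torsions of a residue: intra-residue heavy-atom bonds outside
# rings, reachable from CA without passing through backbone N/C, whose distal
# subtree is non-empty. Returned proximal-to-distal as a list of
# list(tail, head, moving) over serials.
.residue_torsions <- function(s, key) {
  at <- s$atoms
  rows <- which(.res_key(at) == key & at$element != "H")
  ser <- at$serial[rows]
  nm <- at$name[rows]
  b <- s$bonds
  inres <- b[, 1] %in% ser & b[, 2] %in% ser
  bm <- b[inres, , drop = FALSE]
  adj <- list()
  addedge <- function(u, v) {
    adj[[as.character(u)]] <<- c(adj[[as.character(u)]], v)
    adj[[as.character(v)]] <<- c(adj[[as.character(v)]], u)
  }
  for (r in seq_len(nrow(bm))) addedge(bm[r, 1], bm[r, 2])
  ca <- ser[nm == "CA"]
  if (!length(ca)) return(list())
  blocked <- ser[nm %in% c("C", "O", "OXT")]  # carbonyl side is backbone
  # BFS tree from CA
  parent <- setNames(rep(NA_integer_, length(ser)), as.character(ser))
  depth <- setNames(rep(NA_integer_, length(ser)), as.character(ser))
  order_v <- c()
  q <- ca[1]; depth[as.character(ca[1])] <- 0L
  visited <- as.character(ca[1])
  while (length(q)) {
    u <- q[1]; q <- q[-1]
    order_v <- c(order_v, u)
    for (v in adj[[as.character(u)]]) {
      cv <- as.character(v)
      if (cv %in% visited) next
      if (v %in% blocked) { visited <- c(visited, cv); next }
      visited <- c(visited, cv)
      parent[cv] <- u
      depth[cv] <- depth[as.character(u)] + 1L
      q <- c(q, v)
    }
  }
  # ring bonds: edges between two visited vertices that are not tree edges
  ring_members <- character(0)
  for (r in seq_len(nrow(bm))) {
    u <- bm[r, 1]; v <- bm[r, 2]
    if (u %in% blocked || v %in% blocked) next
    cu <- as.character(u); cv <- as.character(v)
    if (!(cu %in% visited) || !(cv %in% visited)) next
    if (is.na(depth[cu]) || is.na(depth[cv])) next
    pu <- unname(parent[cu]); pv <- unname(parent[cv])
    if ((!is.na(pv) && pv == u) || (!is.na(pu) && pu == v)) next
    # back edge: everything on the cycle between u and v is in a ring
    pu <- u; pv <- v
    au <- c(); av <- c()
    while (!is.na(pu)) { au <- c(au, pu); pu <- parent[as.character(pu)] }
    while (!is.na(pv)) { av <- c(av, pv); pv <- parent[as.character(pv)] }
    common <- intersect(au, av)
    lca <- common[1]
    cyc <- c(au[seq_len(match(lca, au))], av[seq_len(match(lca, av))])
    ring_members <- union(ring_members, as.character(cyc))
  }
  # subtree collection
  children <- split(as.integer(names(parent))[!is.na(parent)],
                    as.character(parent[!is.na(parent)]))
  subtree <- function(v) {
    out <- c(); q2 <- v
    while (length(q2)) {
      u <- q2[1]; q2 <- q2[-1]
      out <- c(out, u)
      q2 <- c(q2, children[[as.character(u)]])
    }
    out
  }
  tors <- list()
  for (cv in names(parent)) {
    v <- as.integer(cv)
    u <- parent[cv]
    if (is.na(u)) next
    if (cv %in% ring_members && as.character(u) %in% ring_members) next
    mv <- setdiff(subtree(v), v)
    if (!length(mv)) next
    tors[[length(tors) + 1L]] <- list(tail = unname(u), head = v,
                                      moving = mv,
                                      depth = unname(depth[cv]))
  }
  if (!length(tors)) return(list())
  tors[order(vapply(tors, `[[`, integer(1), "depth"))]
}

# Moving set used for a residue's local strain: all heavy side-chain and
# adduct atoms (everything but backbone N/CA/C/O/OXT).
.residue_moving_set <- function(s, key) {
  at <- s$atoms
  rows <- which(.res_key(at) == key & at$element != "H" &
                  !at$name %in% c("N", "CA", "C", "O", "OXT"))
  at$serial[rows]
}

#' Minimize local strain of a (modified) residue by torsion scanning
#'
#' Performs an exhaustive grid scan over the residue's rotatable side-chain
#' and adduct torsions. The scanned torsion set and step depend on the
#' optimization level: 1 = most distal torsion only, 30 degree steps;
#' 2 = two most distal, 30 degrees; 3 = up to four torsions, 20 degrees;
#' 4 = up to four torsions, 10 degrees. The initial pose is a grid member,
#' so the reported strain never increases. Ties on strain are broken by the
#' smallest total angular displacement from the initial pose.
#'
#' With `probe_baseline = TRUE` and a `baseline` strain value (the residue's
#' pre-modification strain), the scan is skipped when the modification added
#' no strain beyond `baseline + 0.01` A^2.
#'
#' @param s A `ptm_structure`.
#' @param residue Residue key (`"chain|resi|ins"`) or a 1-row subset of
#'   [residue_table()].
#' @param level Optimization level, 1-4 (level 0 must be handled by the
#'   caller; the optimizer is never invoked for it).
#' @param probe_baseline Use the baseline-strain shortcut.
#' @param baseline Pre-modification strain value (A^2), required for the
#'   shortcut.
#' @param neighborhood Strain neighborhood radius (A).
#' @return List of class `optimization_result`: `level`, `torsions` (data
#'   frame `tail`, `head`, `step`, `chosen` offset in degrees),
#'   `strain_before`, `strain_after` (`strain_score` objects),
#'   `baseline_probed`, `scanned`, and the optimized `structure`.
#' @export
optimize_residue <- function(s, residue, level, probe_baseline = FALSE,
                             baseline = NULL, neighborhood = 8.0) {
  if (!is.character(residue)) residue <- residue$key[1]
  if (!level %in% 1:4)
    stop("optimization level must be 1-4 here (0 = optimizer not called)",
         call. = FALSE)
  moving_all <- .residue_moving_set(s, residue)
  empty_result <- function(before, scanned, probed) {
    structure(list(level = level,
                   torsions = data.frame(tail = integer(0), head = integer(0),
                                         step = numeric(0), chosen = numeric(0)),
                   strain_before = before, strain_after = before,
                   baseline_probed = probed, scanned = scanned,
                   structure = s),
              class = "optimization_result")
  }
  if (!length(moving_all))
    return(empty_result(structure(list(value = 0, n_clashes = 0L,
                                       neighborhood = neighborhood,
                                       clashes = data.frame()),
                                  class = "strain_score"), FALSE, FALSE))
  before <- vdw_strain(s, moving_all, neighborhood)
  if (probe_baseline && !is.null(baseline) &&
      before$value <= baseline + .BASELINE_EPS)
    return(empty_result(before, FALSE, TRUE))
  tors <- .residue_torsions(s, residue)
  if (!length(tors)) return(empty_result(before, FALSE, probe_baseline))
  n_t <- c(1L, 2L, 4L, 4L)[level]
  step <- c(30, 30, 20, 10)[level]
  tors <- utils::tail(tors, n_t)  # most distal n_t torsions, proximal first
  offsets <- seq(0, 360 - step, by = step)
  pairs <- .strain_pairs(s, moving_all, neighborhood)
  # static coordinate cache
  all_ser <- unique(c(pairs$i, pairs$j, unlist(lapply(tors, function(t)
    c(t$tail, t$head, t$moving)))))
  P0 <- .coords_of(s, all_ser)
  rownames(P0) <- all_ser
  ii <- match(pairs$i, all_ser)
  jj <- match(pairs$j, all_ser)
  t_tail <- vapply(tors, function(t) match(t$tail, all_ser), integer(1))
  t_head <- vapply(tors, function(t) match(t$head, all_ser), integer(1))
  t_mov <- lapply(tors, function(t) match(t$moving, all_ser))
  k <- length(tors)
  # A pair's distance becomes final after the deepest torsion moving exactly
  # one of its endpoints; pairs untouched by any torsion are scored once.
  # This allows incremental scoring plus branch-and-bound pruning (severities
  # are non-negative, so a partial sum exceeding the best is fatal).
  pair_level <- rep(0L, length(ii))
  for (d in seq_len(k)) {
    ii_in <- ii %in% t_mov[[d]]
    jj_in <- jj %in% t_mov[[d]]
    pair_level[xor(ii_in, jj_in)] <- d
  }
  lvl_pairs <- lapply(0:k, function(d) which(pair_level == d))
  sev_of <- function(P, sel) {
    if (!length(sel)) return(0)
    dd <- sqrt(rowSums((P[ii[sel], , drop = FALSE] -
                          P[jj[sel], , drop = FALSE])^2))
    sum(pmax(0, pairs$rsum[sel] - dd)^2)
  }
  best <- list(value = Inf, disp = Inf, offsets = numeric(k))
  ang_disp <- function(o) sum(pmin(abs(o), 360 - abs(o)))
  acc0 <- sev_of(P0, lvl_pairs[[1]])
  recurse <- function(d, P, chosen, acc) {
    if (acc > best$value + 1e-9) return(invisible())
    if (d > k) {
      disp <- ang_disp(chosen)
      if (acc < best$value - 1e-9 ||
          (abs(acc - best$value) <= 1e-9 && disp < best$disp)) {
        best <<- list(value = acc, disp = disp, offsets = chosen)
      }
      return(invisible())
    }
    for (o in offsets) {
      P2 <- P
      if (o != 0) {
        axis0 <- P[t_tail[d], ]
        axis1 <- P[t_head[d], ]
        mv <- t_mov[[d]]
        Q <- sweep(P[mv, , drop = FALSE], 2, axis0)
        Q <- .rotate_mat(Q, axis1 - axis0, .deg2rad(o))
        P2[mv, ] <- sweep(Q, 2, axis0, `+`)
      }
      recurse(d + 1, P2, c(chosen, o), acc + sev_of(P2, lvl_pairs[[d + 1L]]))
    }
  }
  recurse(1L, P0, numeric(0), acc0)
  # apply the best pose to the structure
  P <- P0
  for (d in seq_len(k)) {
    o <- best$offsets[d]
    if (o == 0) next
    axis0 <- P[t_tail[d], ]; axis1 <- P[t_head[d], ]
    mv <- t_mov[[d]]
    Q <- sweep(P[mv, , drop = FALSE], 2, axis0)
    Q <- .rotate_mat(Q, axis1 - axis0, .deg2rad(o))
    P[mv, ] <- sweep(Q, 2, axis0, `+`)
  }
  im <- match(all_ser, s$atoms$serial)
  s$atoms$x[im] <- P[, 1]; s$atoms$y[im] <- P[, 2]; s$atoms$z[im] <- P[, 3]
  after <- vdw_strain(s, moving_all, neighborhood)
  structure(list(level = level,
                 torsions = data.frame(
                   tail = vapply(tors, `[[`, integer(1), "tail"),
                   head = vapply(tors, `[[`, integer(1), "head"),
                   step = step, chosen = best$offsets),
                 strain_before = before, strain_after = after,
                 baseline_probed = probe_baseline, scanned = TRUE,
                 structure = s),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("<optimization_result> level %d: strain %.4f -> %.4f A^2%s\n",
              x$level, x$strain_before$value, x$strain_after$value,
              if (!x$scanned) " (scan skipped)" else ""))
  if (nrow(x$torsions))
    cat("  chosen offsets:", paste(x$torsions$chosen, collapse = ", "),
        "deg\n")
  invisible(x)
}
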