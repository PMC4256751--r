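# The hierarchical coordinate model. Atoms live in a single data frame
# (one row per atom, PDB column semantics); residues are identified by the
# (chain, resi, insertion code) triple and chains by file order. Bonds are a
# symmetric pair list over atom serials.

.ATOM_COLS <- c("serial", "name", "altloc", "resn", "chain", "resi", "ins",
                "x", "y", "z", "occ", "b", "element", "hetatm", "ptm_tag")

#' Construct a structure object
#'
#' Low-level constructor used by [read_pdb()] and the fixture builders.
#'
#' @param atoms Data frame with one row per atom; required columns
#'   `serial, name, altloc, resn, chain, resi, ins, x, y, z, occ, b, element,
#'   hetatm, ptm_tag`.
#' @param remarks Character vector of REMARK payload lines (provenance).
#' @param source Optional source path.
#' @return An object of class `ptm_structure` with inferred bonds and
#'   N-terminal flags.
#' @export
new_structure <- function(atoms, remarks = character(), source = NA_character_) {
  missing_cols <- setdiff(.ATOM_COLS, names(atoms))
  if (length(missing_cols))
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  atoms <- atoms[, .ATOM_COLS]
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates", call. = FALSE)
  if (anyDuplicated(atoms$serial))
    atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  s <- structure(list(atoms = atoms, bonds = NULL, remarks = remarks,
                      source = source),
                 class = "ptm_structure")
  s$bonds <- infer_bonds(s)
  s
}

#' @export
print.ptm_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("<ptm_structure> %d atoms, %d residues, %d chain(s)\n",
              nrow(x$atoms), nrow(rt), length(unique(x$atoms$chain))))
  if (length(x$remarks)) cat(" remarks:", length(x$remarks), "\n")
  invisible(x)
}

# Unique residue key (chain|resi|ins) per atom row.
.res_key <- function(atoms) paste(atoms$chain, atoms$resi, atoms$ins, sep = "|")

#' Residue-level summary table
#'
#' One row per residue in file order, with chain, number, insertion code,
#' residue name, polymer and N-terminal flags and the PTM tag.
#'
#' @param s A `ptm_structure`.
#' @return Data frame with columns `key, chain, resi, ins, resn, is_polymer,
#'   is_n_terminal, ptm_tag`.
#' @export
residue_table <- function(s) {
  at <- s$atoms
  key <- .res_key(at)
  first <- !duplicated(key)
  rt <- data.frame(key = key[first], chain = at$chain[first],
                   resi = at$resi[first], ins = at$ins[first],
                   resn = at$resn[first], ptm_tag = at$ptm_tag[first],
                   stringsAsFactors = FALSE)
  # polymer: has both N and CA (covers standard and product residues)
  has_n <- tapply(at$name == "N", key, any)[rt$key]
  has_ca <- tapply(at$name == "CA", key, any)[rt$key]
  rt$is_polymer <- as.logical(has_n & has_ca) & !(rt$resn %in% .WATER_RESN)
  rt$is_n_terminal <- FALSE
  for (ch in unique(rt$chain)) {
    i <- which(rt$chain == ch & rt$is_polymer)
    if (length(i)) rt$is_n_terminal[i[1]] <- TRUE
  }
  rownames(rt) <- NULL
  rt
}

# Atom serials of one residue (by key), optionally by name.
.residue_serials <- function(s, key, names = NULL) {
  at <- s$atoms
  sel <- .res_key(at) == key
  if (!is.null(names)) sel <- sel & at$name %in% names
  at$serial[sel]
}

# n x 3 coordinate matrix for the given serials (in that order).
.coords_of <- function(s, serials) {
  i <- match(serials, s$atoms$serial)
  if (anyNA(i)) stop("unknown atom serial(s)", call. = FALSE)
  cbind(x = s$atoms$x[i], y = s$atoms$y[i], z = s$atoms$z[i])
}

# Single named atom of a residue -> serial (NA if absent).
.res_atom_serial <- function(s, key, name) {
  ser <- .residue_serials(s, key, name)
  if (length(ser) == 0) NA_integer_ else ser[1]
}

#' Infer the bond list of a structure
#'
#' Intra-residue bonds come from bundled templates for the 20 standard
#' residues and from the modification catalog for product residues; residues
#' without a template fall back to distance-based bonding (< 1.9 A between
#' heavy atoms, < 2.1 A when S or P is involved). Peptide bonds link
#' consecutive polymer residues of a chain when the C-N distance is < 2.0 A.
#'
#' @param s A `ptm_structure`.
#' @return Two-column integer matrix of atom serials (each bond once,
#'   smaller serial first).
#' @keywords internal
infer_bonds <- function(s) {
  at <- s$atoms
  key <- .res_key(at)
  bonds <- list()
  add_bond <- function(s1, s2) {
    if (!is.na(s1) && !is.na(s2))
      bonds[[length(bonds) + 1L]] <<- c(min(s1, s2), max(s1, s2))
  }
  for (k in unique(key)) {
    rows <- which(key == k)
    resn <- at$resn[rows[1]]
    tmpl <- .bond_template(resn)
    if (!is.null(tmpl)) {
      serial_of <- function(nm) {
        j <- rows[at$name[rows] == nm]
        if (length(j)) at$serial[j[1]] else NA_integer_
      }
      add_bond(serial_of("N"), serial_of("CA"))
      add_bond(serial_of("CA"), serial_of("C"))
      add_bond(serial_of("C"), serial_of("O"))
      add_bond(serial_of("C"), serial_of("OXT"))
      for (b in tmpl) add_bond(serial_of(b[1]), serial_of(b[2]))
      # hydrogens (passengers): attach each H to the nearest heavy atom
      hrows <- rows[at$element[rows] == "H"]
      if (length(hrows)) {
        heavy <- rows[at$element[rows] != "H"]
        for (h in hrows) {
          d2 <- (at$x[heavy] - at$x[h])^2 + (at$y[heavy] - at$y[h])^2 +
            (at$z[heavy] - at$z[h])^2
          add_bond(at$serial[h], at$serial[heavy[which.min(d2)]])
        }
      }
    } else {
      # distance-based fallback
      if (length(rows) > 1) {
        P <- cbind(at$x[rows], at$y[rows], at$z[rows])
        D <- as.matrix(stats::dist(P))
        sp <- at$element[rows] %in% c("S", "P")
        for (i in seq_along(rows)) for (j in seq_len(i - 1L)) {
          cut <- if (sp[i] || sp[j]) 2.1 else 1.9
          if (D[i, j] < cut) add_bond(at$serial[rows[i]], at$serial[rows[j]])
        }
      }
    }
  }
  # peptide bonds between consecutive polymer residues within each chain
  rt <- residue_table(s)
  for (ch in unique(rt$chain)) {
    idx <- which(rt$chain == ch & rt$is_polymer)
    if (length(idx) < 2) next
    for (m in seq_len(length(idx) - 1L)) {
      k1 <- rt$key[idx[m]]; k2 <- rt$key[idx[m + 1L]]
      c1 <- .res_atom_serial(s, k1, "C")
      n2 <- .res_atom_serial(s, k2, "N")
      if (is.na(c1) || is.na(n2)) next
      d <- .vnorm(.coords_of(s, n2)[1, ] - .coords_of(s, c1)[1, ])
      if (d < 2.0) add_bond(c1, n2)
    }
  }
  if (!length(bonds)) return(matrix(integer(0), ncol = 2))
  bm <- unique(do.call(rbind, bonds))
  bm[bm[, 1] != bm[, 2], , drop = FALSE]
}

# Template lookup: standard residues, then catalog product residues.
.bond_template <- function(resn) {
  t <- .SC_BONDS[[resn]]
  if (!is.null(t)) return(t)
  .catalog_bond_template(resn)
}

# Adjacency list over serials from the bond matrix.
.bond_adjacency <- function(s) {
  adj <- split(c(s$bonds[, 2], s$bonds[, 1]), c(s$bonds[, 1], s$bonds[, 2]))
  adj
}

# Serials within `depth` bonds of each serial in `from` (including `from`).
.bonded_within <- function(adj, from, depth) {
  seen <- as.character(from)
  frontier <- seen
  for (d in seq_len(depth)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(as.character(nxt), seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
  }
  as.integer(seen)
}

# Append atoms (data frame rows with the .ATOM_COLS schema minus serial);
# serials are assigned past the current maximum. Returns the structure
# (bonds NOT re-inferred; caller decides).
.append_atoms <- function(s, newdf) {
  base <- if (nrow(s$atoms)) max(s$atoms$serial) else 0L
  newdf$serial <- base + seq_len(nrow(newdf))
  s$atoms <- rbind(s$atoms, newdf[, .ATOM_COLS])
  rownames(s$atoms) <- NULL
  s
}

.remove_atoms <- function(s, serials) {
  s$atoms <- s$atoms[!s$atoms$serial %in% serials, ]
  rownames(s$atoms) <- NULL
  if (!is.null(s$bonds) && nrow(s$bonds))
    s$bonds <- s$bonds[!(s$bonds[, 1] %in% serials | s$bonds[, 2] %in% serials),
                       , drop = FALSE]
  s
}

# Merge two structures (e.g. peptide + cage); chains kept as-is, serials and
# bonds re-derived.
#' Combine two structures into one
#'
#' Atoms of `b` are appended after `a` (chain identifiers are kept, so give
#' the parts distinct chains); serials are reassigned and bonds re-inferred.
#'
#' @param a,b `ptm_structure` objects.
#' @return A single combined `ptm_structure`.
#' @export
combine_structures <- function(a, b) {
  at <- rbind(a$atoms, b$atoms)
  at$serial <- seq_len(nrow(at))
  new_structure(at, remarks = c(a$remarks, b$remarks), source = a$source)
}
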