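# PDB v3.3 fixed-column reading and writing (ATOM/HETATM/TER/REMARK/MODEL).

.parse_pdb_atom_line <- function(line, lineno) {
  pad <- function(x, n) formatC(x, width = n, flag = "-")
  line <- pad(line, 80)
  num <- function(from, to, what, integer = FALSE) {
    f <- substr(line, from, to)
    v <- suppressWarnings(if (integer) as.integer(f) else as.numeric(f))
    if (is.na(v)) stop(sprintf("unparseable %s in ATOM record at line %d",
                               what, lineno), call. = FALSE)
    v
  }
  serial <- num(7, 11, "serial", integer = TRUE)
  name <- trimws(substr(line, 13, 16))
  altloc <- trimws(substr(line, 17, 17))
  resn <- trimws(substr(line, 18, 20))
  chain <- substr(line, 22, 22)
  resi <- num(23, 26, "residue number", integer = TRUE)
  ins <- trimws(substr(line, 27, 27))
  x <- num(31, 38, "x"); y <- num(39, 46, "y"); z <- num(47, 54, "z")
  occ <- suppressWarnings(as.numeric(substr(line, 55, 60)))
  b <- suppressWarnings(as.numeric(substr(line, 61, 66)))
  element <- toupper(trimws(substr(line, 77, 78)))
  if (element == "") element <- .element_from_name(name)
  if (element == "")
    stop(sprintf("cannot determine element in ATOM record at line %d", lineno),
         call. = FALSE)
  list(serial = serial, name = name, altloc = altloc, resn = resn,
       chain = chain, resi = resi, ins = ins, x = x, y = y, z = z,
       occ = if (is.na(occ)) 1 else occ, b = if (is.na(b)) 0 else b,
       element = element)
}

# Heuristic element inference for files lacking the element column.
.element_from_name <- function(name) {
  two <- toupper(substr(gsub("[0-9']", "", name), 1, 2))
  if (two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "SE", "CU", "NI", "CO"))
    return(two)
  one <- substr(gsub("[0-9']", "", name), 1, 1)
  toupper(one)
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records of one model into a structure object. Alternate
#' locations are resolved by keeping the highest-occupancy conformer of each
#' (residue, atom name); residue numbering and insertion codes are taken
#' verbatim from the file. Bonds are inferred from residue templates plus
#' distance-checked peptide links, and the first polymer residue of each
#' chain is flagged as N-terminal.
#'
#' @param path Path to a PDB file.
#' @param model_index Zero-based model index for multi-model files
#'   (default 0: first model).
#' @return A `ptm_structure`.
#' @export
read_pdb <- function(path, model_index = 0) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  # model slicing
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts)) {
    if (model_index + 1 > length(model_starts))
      stop("model_index ", model_index, " out of range (",
           length(model_starts), " models)", call. = FALSE)
    from <- model_starts[model_index + 1]
    ends <- grep("^ENDMDL", lines)
    to <- ends[ends > from]
    to <- if (length(to)) to[1] else length(lines)
    lines_model <- lines[from:to]
  } else lines_model <- lines
  sel <- grep("^(ATOM  |HETATM)", lines_model)
  if (!length(sel)) stop("no atoms in model", call. = FALSE)
  recs <- lapply(sel, function(i)
    c(.parse_pdb_atom_line(lines_model[i], i),
      list(hetatm = startsWith(lines_model[i], "HETATM"))))
  at <- data.frame(
    serial = vapply(recs, `[[`, integer(1), "serial"),
    name = vapply(recs, `[[`, character(1), "name"),
    altloc = vapply(recs, `[[`, character(1), "altloc"),
    resn = vapply(recs, `[[`, character(1), "resn"),
    chain = vapply(recs, `[[`, character(1), "chain"),
    resi = vapply(recs, `[[`, integer(1), "resi"),
    ins = vapply(recs, `[[`, character(1), "ins"),
    x = vapply(recs, `[[`, numeric(1), "x"),
    y = vapply(recs, `[[`, numeric(1), "y"),
    z = vapply(recs, `[[`, numeric(1), "z"),
    occ = vapply(recs, `[[`, numeric(1), "occ"),
    b = vapply(recs, `[[`, numeric(1), "b"),
    element = vapply(recs, `[[`, character(1), "element"),
    hetatm = vapply(recs, `[[`, logical(1), "hetatm"),
    ptm_tag = "", stringsAsFactors = FALSE)
  # altloc resolution: highest occupancy per (residue, atom name)
  akey <- paste(.res_key(at), at$name)
  if (anyDuplicated(akey)) {
    keep <- rep(TRUE, nrow(at))
    for (k in unique(akey[duplicated(akey)])) {
      rows <- which(akey == k)
      best <- rows[which.max(at$occ[rows])]
      keep[setdiff(rows, best)] <- FALSE
    }
    at <- at[keep, ]
  }
  at$serial <- seq_len(nrow(at))
  remarks <- sub("^REMARK 999 ?", "", grep("^REMARK 999", lines, value = TRUE))
  new_structure(at, remarks = remarks, source = path)
}

.format_atom_name <- function(name, element) {
  # standard alignment: element occupies columns 13-14
  if (nchar(name) >= 4) return(substr(name, 1, 4))
  if (nchar(element) == 1) formatC(paste0(" ", name), width = -4)
  else formatC(name, width = -4)
}

#' Write a structure as PDB
#'
#' Emits PDB v3.3 ATOM/HETATM records with 8.3 fixed-point coordinates, TER
#' after each chain and REMARK 999 provenance lines listing applied
#' modifications. Modified residues (non-empty `ptm_tag` with a renamed
#' residue) are written as HETATM. Serialization is deterministic:
#' writing the same structure twice gives byte-identical files.
#'
#' @param s A non-empty `ptm_structure`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(s, path) {
  at <- s$atoms
  if (!nrow(at)) stop("refusing to write an empty structure", call. = FALSE)
  if (any(nchar(at$name) > 4))
    stop("atom name longer than 4 characters: ",
         paste(unique(at$name[nchar(at$name) > 4]), collapse = ", "),
         call. = FALSE)
  out <- character(0)
  if (length(s$remarks))
    out <- c(out, sprintf("REMARK 999 %s", s$remarks))
  rt <- residue_table(s)
  serial_out <- 0L
  last_chain <- NULL
  lines <- character(0)
  key <- .res_key(at)
  ter_after <- function(row) {
    serial_out <<- serial_out + 1L
    sprintf("TER   %5d      %3s %1s%4d%1s",
            serial_out, row$resn, row$chain, row$resi,
            ifelse(row$ins == "", " ", row$ins))
  }
  prev_row <- NULL
  for (i in seq_len(nrow(at))) {
    if (!is.null(last_chain) && at$chain[i] != last_chain) {
      lines <- c(lines, ter_after(prev_row))
    }
    serial_out <- serial_out + 1L
    rec <- if (at$hetatm[i]) "HETATM" else "ATOM  "
    lines <- c(lines, sprintf(
      "%s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, serial_out, .format_atom_name(at$name[i], at$element[i]),
      ifelse(at$altloc[i] == "", " ", at$altloc[i]),
      at$resn[i], at$chain[i], at$resi[i],
      ifelse(at$ins[i] == "", " ", at$ins[i]),
      at$x[i], at$y[i], at$z[i], at$occ[i], at$b[i], at$element[i]))
    last_chain <- at$chain[i]
    prev_row <- at[i, ]
  }
  lines <- c(lines, ter_after(prev_row), "END")
  writeLines(c(out, lines), path)
  invisible(path)
}
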