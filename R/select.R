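# Mini selection grammar over atoms:
#   chain <id> | resn <code>[+<code>...] | resi <n>[-<m>][,<...>] | name <atom>
# combined with AND / OR / NOT and parentheses. Keywords are
# case-insensitive; values are matched case-insensitively for resn/name.

.tokenize_selection <- function(expr) {
  expr <- gsub("\\(", " ( ", expr)
  expr <- gsub("\\)", " ) ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  toks[toks != ""]
}

# Recursive-descent parser; returns a logical vector over atom rows.
.parse_or <- function(st) {
  v <- .parse_and(st)
  while (!st$eof() && toupper(st$peek()) == "OR") {
    st$next_tok()
    v <- v | .parse_and(st)
  }
  v
}

.parse_and <- function(st) {
  v <- .parse_not(st)
  while (!st$eof() && toupper(st$peek()) == "AND") {
    st$next_tok()
    v <- v & .parse_not(st)
  }
  v
}

.parse_not <- function(st) {
  if (!st$eof() && toupper(st$peek()) == "NOT") {
    st$next_tok()
    return(!.parse_not(st))
  }
  .parse_primary(st)
}

.parse_primary <- function(st) {
  if (st$eof()) stop("selection syntax error: unexpected end of expression",
                     call. = FALSE)
  tok <- st$next_tok()
  if (tok == "(") {
    v <- .parse_or(st)
    if (st$eof() || st$next_tok() != ")")
      stop("selection syntax error: missing ')'", call. = FALSE)
    return(v)
  }
  kw <- toupper(tok)
  at <- st$atoms
  if (!kw %in% c("CHAIN", "RESN", "RESI", "NAME"))
    stop("selection syntax error: unexpected token '", tok, "'", call. = FALSE)
  if (st$eof()) stop("selection syntax error: '", tok, "' needs a value",
                     call. = FALSE)
  val <- st$next_tok()
  parts <- strsplit(val, "[+,]")[[1]]
  switch(kw,
    CHAIN = at$chain %in% parts,
    RESN = toupper(at$resn) %in% toupper(parts),
    NAME = toupper(at$name) %in% toupper(parts),
    RESI = {
      sel <- rep(FALSE, nrow(at))
      for (p in parts) {
        m <- regmatches(p, regexec("^(-?[0-9]+)(?:-(-?[0-9]+))?$", p))[[1]]
        if (!length(m)) stop("selection syntax error: bad resi range '", p,
                             "'", call. = FALSE)
        lo <- as.integer(m[2])
        hi <- if (m[3] == "") lo else as.integer(m[3])
        sel <- sel | (at$resi >= lo & at$resi <= hi)
      }
      sel
    })
}

#' Select atoms by expression
#'
#' Evaluates a small selection grammar (`chain`, `resn`, `resi`, `name`
#' clauses combined with `and`/`or`/`not` and parentheses) against the atom
#' table. `resi` accepts ranges (`1-3`) and comma lists; `resn`/`name`
#' accept `+`-separated alternatives.
#'
#' @param s A `ptm_structure`.
#' @param expr Selection expression, e.g. `"resn LYS and name NZ"`.
#' @return Integer vector of matching atom serials (possibly empty).
#' @examples
#' \dontrun{select_atoms(s, "resi 1-3 and not name CA")}
#' @export
select_atoms <- function(s, expr) {
  toks <- .tokenize_selection(expr)
  if (!length(toks)) stop("empty selection expression", call. = FALSE)
  pos <- 0L
  st <- list(
    atoms = s$atoms,
    peek = function() toks[pos + 1L],
    next_tok = function() { pos <<- pos + 1L; toks[pos] },
    eof = function() pos >= length(toks)
  )
  v <- .parse_or(st)
  if (!st$eof())
    stop("selection syntax error: trailing token '", st$peek(), "'",
         call. = FALSE)
  s$atoms$serial[v]
}
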