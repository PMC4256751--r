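# The modification catalog: ten PTM classes, declaratively defined in a
# versioned, human-readable JSON file (inst/extdata/ptm_catalog.json) so the
# chemistry can be extended without code changes.

.catalog_env <- new.env(parent = emptyenv())

.catalog_path <- function() {
  p <- system.file("extdata", "ptm_catalog.json", package = "ptmgraft")
  if (p == "") {
    # source-tree fallback (development)
    p <- file.path("inst", "extdata", "ptm_catalog.json")
  }
  p
}

.load_catalog <- function() {
  if (!is.null(.catalog_env$catalog)) return(.catalog_env$catalog)
  raw <- jsonlite::fromJSON(.catalog_path(), simplifyVector = FALSE)
  vars <- raw$variants
  # validation
  classes <- vapply(vars, `[[`, character(1), "class")
  for (cl in unique(classes)) {
    defs <- vapply(vars[classes == cl], `[[`, logical(1), "default")
    if (sum(defs) != 1)
      stop("catalog invalid: class ", cl, " must have exactly one default",
           call. = FALSE)
  }
  for (v in vars) {
    for (tg in v$targets)
      if (nchar(tg$product) > 3)
        stop("catalog invalid: product code > 3 chars: ", tg$product,
             call. = FALSE)
    seen <- c("@A", "@B", "@C")
    for (b in v$build) {
      if (nchar(b$name) > 4)
        stop("catalog invalid: atom name > 4 chars: ", b$name, call. = FALSE)
      if (b$length <= 0.8 || b$length >= 2.5)
        stop("catalog invalid: bond length out of (0.8, 2.5): ", b$name,
             call. = FALSE)
      if (b$angle <= 0 || b$angle >= 180)
        stop("catalog invalid: bond angle out of (0, 180): ", b$name,
             call. = FALSE)
      seen <- c(seen, b$name)
    }
  }
  .catalog_env$catalog <- list(version = raw$catalog_version, variants = vars)
  .catalog_env$catalog
}

#' List the supported PTM classes and variants
#'
#' @return A data frame of class `ptm_catalog_index` with one row per
#'   variant: `ptm_class`, `variant`, `default`, `product` (comma-joined for
#'   multi-target classes), `targets` (target residues), `n_term_capable`
#'   and `charge_delta`.
#' @examples
#' idx <- list_ptms()
#' unique(idx$ptm_class)   # the ten supported classes
#' @export
list_ptms <- function() {
  cat <- .load_catalog()
  rows <- lapply(cat$variants, function(v) data.frame(
    ptm_class = v$class, variant = v$variant, default = isTRUE(v$default),
    product = paste(unique(vapply(v$targets, `[[`, character(1), "product")),
                    collapse = ","),
    targets = paste(unique(vapply(v$targets, `[[`, character(1), "resn")),
                    collapse = ","),
    n_term_capable = isTRUE(v$n_term_capable),
    charge_delta = as.integer(v$charge_delta),
    stringsAsFactors = FALSE))
  idx <- do.call(rbind, rows)
  class(idx) <- c("ptm_catalog_index", "data.frame")
  attr(idx, "catalog_version") <- cat$version
  idx
}

#' @export
print.ptm_catalog_index <- function(x, ...) {
  cat(sprintf("PTM catalog v%s: %d classes, %d variants\n",
              attr(x, "catalog_version"), length(unique(x$ptm_class)),
              nrow(x)))
  for (cl in unique(x$ptm_class)) {
    sub <- x[x$ptm_class == cl, ]
    vs <- ifelse(sub$default, paste0(sub$variant, "*"), sub$variant)
    cat(sprintf("  %-22s -> %-8s [%s]%s\n", cl,
                paste(unique(sub$targets), collapse = ","),
                paste(vs, collapse = ", "),
                ifelse(any(sub$n_term_capable), " (+N-term, excl. Pro)", "")))
  }
  cat("(* = default variant)\n")
  invisible(x)
}

#' Retrieve a fully resolved PTM definition
#'
#' @param ptm_class One of the ten supported classes (see [list_ptms()]).
#' @param variant Variant name; omitted/NULL selects the class default.
#' @return An object of class `ptm_definition`: a list with fields
#'   `ptm_class`, `variant`, `target_resn`, `targets` (per-residue target
#'   atom, anchor chain and product code), `n_term_capable`, `atoms_added`,
#'   `atoms_removed`, `element_swaps`, `extra_bonds`, `charge_delta`,
#'   `stereocenters` and (for deferred-stereochemistry variants)
#'   `choice_of`.
#' @examples
#' get_definition("nitration")
#' get_definition("methionine_oxidation", "R")
#' @export
get_definition <- function(ptm_class, variant = NULL) {
  cat <- .load_catalog()
  classes <- vapply(cat$variants, `[[`, character(1), "class")
  if (!ptm_class %in% classes)
    stop("unknown PTM class '", ptm_class, "'; valid classes: ",
         paste(sort(unique(classes)), collapse = ", "), call. = FALSE)
  sub <- cat$variants[classes == ptm_class]
  vnames <- vapply(sub, `[[`, character(1), "variant")
  v <- if (is.null(variant)) {
    sub[[which(vapply(sub, function(z) isTRUE(z$default), logical(1)))]]
  } else {
    if (!variant %in% vnames)
      stop("unknown variant '", variant, "' for class ", ptm_class,
           "; valid variants: ", paste(vnames, collapse = ", "),
           call. = FALSE)
    sub[[match(variant, vnames)]]
  }
  defn <- list(
    ptm_class = v$class,
    variant = v$variant,
    is_default = isTRUE(v$default),
    target_resn = unique(vapply(v$targets, `[[`, character(1), "resn")),
    targets = v$targets,
    n_term_capable = isTRUE(v$n_term_capable),
    atoms_added = v$build,
    atoms_removed = unlist(v$removes),
    element_swaps = v$swaps,
    extra_bonds = v$extra_bonds,
    charge_delta = as.integer(v$charge_delta),
    stereocenters = v$stereocenters,
    choice_of = unlist(v$choice_of)
  )
  class(defn) <- "ptm_definition"
  defn
}

#' @export
print.ptm_definition <- function(x, ...) {
  cat(sprintf("<ptm_definition> %s / %s%s\n", x$ptm_class, x$variant,
              if (x$is_default) " (default)" else ""))
  cat("  targets:",
      paste(vapply(x$targets, function(t)
        sprintf("%s %s -> %s", t$resn, t$atom, t$product), character(1)),
        collapse = "; "), "\n")
  cat(sprintf("  +%d atoms, -%d atoms, %d swaps, charge %+d\n",
              length(x$atoms_added), length(x$atoms_removed),
              length(x$element_swaps), x$charge_delta))
  if (length(x$stereocenters))
    cat("  stereocenters:",
        paste(vapply(x$stereocenters, function(sc)
          paste0(sc$center, "=", sc$label), character(1)), collapse = ", "),
        "\n")
  invisible(x)
}

# Target record of a definition for a residue name (NULL if none).
.defn_targets_for <- function(defn, resn) {
  Filter(function(t) t$resn == resn, defn$targets)
}

# Product bond template lookup used by infer_bonds(): for a product residue
# code, the base residue's template plus swap renames plus built-atom bonds.
.catalog_bond_template <- function(resn) {
  cat <- tryCatch(.load_catalog(), error = function(e) NULL)
  if (is.null(cat)) return(NULL)
  for (v in cat$variants) {
    if (!is.null(v$choice_of)) next  # deferred records carry no build
    for (tg in v$targets) {
      if (tg$product != resn) next
      base <- .SC_BONDS[[tg$resn]]
      if (is.null(base)) return(NULL)
      # apply swap renames
      for (sw in v$swaps) {
        if (!is.null(sw$new_name))
          base <- lapply(base, function(b) {
            b[b == sw$name] <- sw$new_name
            b
          })
      }
      # remove bonds to removed atoms
      rem <- unlist(v$removes)
      if (length(rem))
        base <- Filter(function(b) !any(b %in% rem), base)
      # built atoms bond their third reference; anchors resolve per target
  resolve <- function(nm) switch(nm, "@A" = tg$anchors[[1]],
                                     "@B" = tg$anchors[[2]],
                                     "@C" = tg$anchors[[3]], nm)
      for (b in v$build)
        base <- c(base, list(c(b$name, resolve(b$refs[[3]]))))
      for (eb in v$extra_bonds)
        base <- c(base, list(c(resolve(eb[[1]]), resolve(eb[[2]]))))
      return(base)
    }
  }
  NULL
}

# All product codes in the catalog (used to flag already-modified residues).
.catalog_product_codes <- function() {
  cat <- .load_catalog()
  unique(unlist(lapply(cat$variants, function(v)
    vapply(v$targets, `[[`, character(1), "product"))))
}
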