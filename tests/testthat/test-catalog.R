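test_that("the catalog exposes exactly ten classes with correct defaults", {
  idx <- list_ptms()
  expect_setequal(unique(idx$ptm_class),
                  c("acetylation", "carbamylation", "citrullination",
                    "cysteine_oxidation", "mda_adduct",
                    "methionine_oxidation", "methylation", "nitration",
                    "proline_hydroxylation", "phosphorylation"))
  expect_identical(length(unique(idx$ptm_class)), 10L)
  # exactly one default per class, at least one variant each
  for (cl in unique(idx$ptm_class))
    expect_identical(sum(idx$default[idx$ptm_class == cl]), 1L)
  expect_identical(idx$variant[idx$ptm_class == "mda_adduct" & idx$default],
                   "MAA")
  expect_setequal(idx$variant[idx$ptm_class == "methionine_oxidation"],
                  c("R", "S", "racemic-choice"))
})

test_that("definitions resolve with full recipes and helpful errors", {
  d <- get_definition("nitration")
  expect_identical(d$target_resn, "TYR")
  expect_identical(unique(vapply(d$targets, `[[`, character(1), "product")),
                   "NIY")
  expect_setequal(vapply(d$targets, `[[`, character(1), "atom"),
                  c("CE1", "CE2"))  # the two ortho ring carbons
  els <- vapply(d$atoms_added, `[[`, character(1), "element")
  expect_identical(sort(els), c("N", "O", "O"))
  expect_identical(d$charge_delta, 0L)

  m <- get_definition("methionine_oxidation", "R")
  expect_identical(length(m$atoms_added), 1L)
  expect_identical(m$atoms_added[[1]]$element, "O")
  expect_identical(m$targets[[1]]$atom, "SD")
  expect_identical(m$targets[[1]]$product, "SME")
  expect_identical(m$stereocenters[[1]]$label, "R")

  cit <- get_definition("citrullination")
  expect_identical(length(cit$atoms_added), 0L)
  expect_identical(cit$element_swaps[[1]]$name, "NH1")
  expect_identical(cit$element_swaps[[1]]$element, "O")
  expect_identical(cit$charge_delta, -1L)

  expect_error(get_definition("glycosylation"), "valid classes")
  expect_error(get_definition("nitration", "meta"), "valid variants")
})

test_that("every variant conserves the heavy-atom ledger on an ideal target", {
  idx <- list_ptms()
  for (i in seq_len(nrow(idx))) {
    cl <- idx$ptm_class[i]; v <- idx$variant[i]
    tg <- strsplit(idx$targets[i], ",")[[1]][1]
    seq1 <- names(which(ptmgraft:::.AA1TO3 == tg))
    s <- build_peptide(paste0("A", seq1, "A"))
    key <- res_key_of(s, "A", 2)
    n0 <- length(res_serials(s, key))
    res <- apply_ptm(s, key, get_definition(cl, v),
                     modification_options(cl, v))
    expect_identical(res$entry$outcome, "modified",
                     info = paste(cl, v))
    n1 <- length(res_serials(res$structure, key))
    expect_identical(n1 - n0, res$entry$n_added - res$entry$n_removed,
                     info = paste(cl, v))
    defn <- get_definition(cl, v)
    if (!length(defn$choice_of))
      expect_identical(res$entry$n_added, length(defn$atoms_added),
                       info = paste(cl, v))
  }
})

test_that("realized internal coordinates match each recipe to 1e-4", {
  idx <- list_ptms()
  concrete <- idx[!(idx$ptm_class == "methionine_oxidation" &
                      idx$variant == "racemic-choice"), ]
  for (i in seq_len(nrow(concrete))) {
    cl <- concrete$ptm_class[i]; v <- concrete$variant[i]
    tg <- strsplit(concrete$targets[i], ",")[[1]][1]
    seq1 <- names(which(ptmgraft:::.AA1TO3 == tg))
    s <- build_peptide(paste0("A", seq1, "A"))
    key <- res_key_of(s, "A", 2)
    defn <- get_definition(cl, v)
    res <- apply_ptm(s, key, defn, modification_options(cl, v))
    s2 <- res$structure
    target <- ptmgraft:::.defn_targets_for(defn, ptmgraft:::.AA1TO3[[seq1]])
    ti <- if (is.na(res$entry$position)) 1L else
      which(vapply(target, function(t) identical(as.integer(t$position),
                                                res$entry$position),
                   logical(1)))[1]
    anchors <- target[[ti]]$anchors
    resolve <- function(nm) switch(nm, "@A" = anchors[[1]],
                                   "@B" = anchors[[2]],
                                   "@C" = anchors[[3]], nm)
    for (b in defn$atoms_added) {
      pr <- lapply(b$refs, function(r) res_atom_xyz(s2, key, resolve(r)))
      pd <- res_atom_xyz(s2, key, b$name)
      expect_equal(measure_distance(pr[[3]], pd), b$length,
                   tolerance = 1e-4, info = paste(cl, v, b$name))
      expect_equal(measure_angle(pr[[2]], pr[[3]], pd), b$angle,
                   tolerance = 1e-4, info = paste(cl, v, b$name))
      dphi <- ((measure_dihedral(pr[[1]], pr[[2]], pr[[3]], pd) -
                  b$dihedral + 180) %% 360) - 180
      expect_lt(abs(dphi), 1e-4)
    }
  }
})

test_that("the formal-charge ledger follows the documented chemistry", {
  expected <- c(acetylation = -1L, carbamylation = -1L, citrullination = -1L,
                cysteine_oxidation = 0L, mda_adduct = -1L,
                methionine_oxidation = 0L, methylation = 0L, nitration = 0L,
                proline_hydroxylation = 0L, phosphorylation = -2L)
  idx <- list_ptms()
  for (cl in names(expected))
    expect_true(all(idx$charge_delta[idx$ptm_class == cl] == expected[[cl]]),
                info = cl)
})

test_that("declared stereocenters are realized by application", {
  cases <- list(
    list("methionine_oxidation", "R", "M"),
    list("methionine_oxidation", "S", "M"),
    list("cysteine_oxidation", "sulfinic-R", "C"),
    list("cysteine_oxidation", "sulfinic-S", "C"),
    list("mda_adduct", "FAAB-R", "K"),
    list("mda_adduct", "FAAB-S", "K"),
    list("proline_hydroxylation", "4R", "P"),
    list("proline_hydroxylation", "4S", "P"))
  for (cs in cases) {
    s <- build_peptide(paste0("A", cs[[3]], "A"))
    defn <- get_definition(cs[[1]], cs[[2]])
    res <- apply_ptm(s, res_key_of(s, "A", 2), defn,
                     modification_options(cs[[1]], cs[[2]]))
    want <- vapply(defn$stereocenters, `[[`, character(1), "label")
    expect_identical(res$entry$stereo, paste(want, collapse = ","),
                     info = paste(cs[[1]], cs[[2]]))
  }
})
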