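test_that("candidate discovery: skip rules, N-terminal rules, stable order", {
  # one of three tyrosines already nitrated -> two candidates remain
  s <- build_peptide("YAYAY")
  r1 <- modify_structure(s, modification_options("nitration",
                                                 selection = "resi 1"))
  s2 <- r1$structure
  cands <- find_candidates(s2, modification_options("nitration"))
  expect_identical(nrow(cands), 2L)
  expect_identical(cands$resi, c(3L, 5L))
  det <- find_candidates(s2, modification_options("nitration"), detail = TRUE)
  expect_identical(det$status[det$resi == 1], "skipped_already_modified")
  # proline-initiated chain: N-terminus is never a candidate
  p <- build_peptide("PAK")
  detp <- find_candidates(p, modification_options("acetylation",
                                                  include_n_termini = TRUE),
                          detail = TRUE)
  expect_identical(detp$status[detp$mode == "nterm"],
                   "skipped_not_n_terminal")
  expect_false("nterm" %in% detp$mode[detp$status == "candidate"])
  # surface filter: two exposed lysines + one caged -> two candidates
  comb <- combine_structures(build_peptide("KAK", chain = "A"),
                             shift_structure(
                               build_cage(build_peptide("K", chain = "B"),
                                          7.6, 300), c(60, 0, 0)))
  opts <- modification_options("mda_adduct", surface_cutoff = 25)
  sa <- compute_sasa(comb)
  cands2 <- find_candidates(comb, opts, sa)
  expect_identical(nrow(cands2), 2L)
  expect_identical(unique(cands2$chain), "A")
  det2 <- find_candidates(comb, opts, sa, detail = TRUE)
  expect_identical(det2$status[det2$chain == "B"], "skipped_buried")
})

test_that("grafting bookkeeping: nitration adds N+2O, citrullination swaps", {
  y <- build_peptide("AYA")
  key <- res_key_of(y, "A", 2)
  n0 <- length(res_serials(y, key))
  r <- apply_ptm(y, key, get_definition("nitration"),
                 modification_options("nitration"))
  expect_identical(length(res_serials(r$structure, key)) - n0, 3L)
  at2 <- r$structure$atoms
  expect_identical(unique(at2$resn[at2$serial %in%
                                     res_serials(r$structure, key)]), "NIY")
  a <- build_peptide("ARA")
  keya <- res_key_of(a, "A", 2)
  els0 <- table(a$atoms$element[a$atoms$serial %in% res_serials(a, keya)])
  ra <- apply_ptm(a, keya, get_definition("citrullination"),
                  modification_options("citrullination"))
  sa2 <- ra$structure
  els1 <- table(sa2$atoms$element[sa2$atoms$serial %in%
                                    res_serials(sa2, keya)])
  expect_identical(length(res_serials(sa2, keya)),
                   length(res_serials(a, keya)))
  expect_identical(unname(els1["N"]), unname(els0["N"]) - 1L)
  expect_identical(unname(els1["O"]), unname(els0["O"]) + 1L)
  expect_identical(unique(sa2$atoms$resn[sa2$atoms$serial %in%
                                           res_serials(sa2, keya)]), "CIR")
})

test_that("repeated application is a no-op with the right skip reason", {
  y <- build_peptide("AYA")
  key <- res_key_of(y, "A", 2)
  r1 <- apply_ptm(y, key, get_definition("nitration"),
                  modification_options("nitration"))
  r2 <- apply_ptm(r1$structure, key, get_definition("nitration"),
                  modification_options("nitration"))
  expect_identical(r2$entry$outcome, "skipped_already_modified")
  expect_identical(r2$structure$atoms, r1$structure$atoms)
})

test_that("modify_structure orchestrates, reports and stays idempotent", {
  # no targets at all: empty report, no error
  r0 <- modify_structure(build_peptide("AGA"),
                         modification_options("nitration"))
  expect_identical(attr(r0$report, "totals")$candidates, 0L)
  # K-A-K with MAA: 2 modified, total charge -2
  res <- modify_structure(build_peptide("KAK"),
                          modification_options("mda_adduct"))
  t <- attr(res$report, "totals")
  expect_identical(t$modified, 2L)
  expect_identical(t$total_charge_delta, -2L)
  expect_true(all(res$report$resn_after[res$report$outcome == "modified"] ==
                    "MM1"))
  # second run: zero modified
  res2 <- modify_structure(res$structure, modification_options("mda_adduct"))
  expect_identical(attr(res2$report, "totals")$modified, 0L)
  # report partitions candidates
  expect_identical(t$modified + t$skipped, t$candidates)
  # provenance remarks present
  expect_true(any(grepl("PTM mda_adduct/MAA", res$structure$remarks)))
})

test_that("unmodified residues keep bitwise-identical coordinates", {
  s <- build_peptide("KAKA")
  res <- modify_structure(s, modification_options("acetylation",
                                                  selection = "resi 1"))
  untouched <- s$atoms$serial[s$atoms$resi != 1]
  expect_identical(ptmgraft:::.coords_of(res$structure, untouched),
                   ptmgraft:::.coords_of(s, untouched))
})

test_that("outcome multiset is independent of chain order (no cutoff)", {
  a <- build_peptide("KYK", chain = "A")
  b <- build_peptide("YKY", chain = "B")
  ab <- combine_structures(a, b)
  ba <- combine_structures(b, a)
  for (cl in c("mda_adduct", "nitration")) {
    r1 <- modify_structure(ab, modification_options(cl))
    r2 <- modify_structure(ba, modification_options(cl))
    o1 <- sort(paste(r1$report$chain, r1$report$resi, r1$report$outcome))
    o2 <- sort(paste(r2$report$chain, r2$report$resi, r2$report$outcome))
    expect_identical(o1, o2)
  }
})

test_that("N-terminal capping tags without renaming and respects the recipe", {
  s <- build_peptide("SAK")
  res <- modify_structure(s, modification_options("acetylation",
                                                  include_n_termini = TRUE))
  rep <- res$report
  nterm <- rep[rep$mode == "nterm", ]
  expect_identical(nterm$outcome, "modified")
  expect_identical(nterm$resn_after, "SER")  # name unchanged
  at <- res$structure$atoms
  ser1 <- at[paste(at$chain, at$resi, sep = "|") == "A|1", ]
  expect_true(all(c("CNT", "ONT", "CMT") %in% ser1$name))
  expect_true(all(nzchar(ser1$ptm_tag)))
  # the lysine side chain was also acetylated in the same pass
  expect_true("ALY" %in% at$resn)
})

test_that("disulfide-bonded cysteines are not oxidation candidates", {
  a <- build_peptide("AC", chain = "A")
  key <- res_key_of(a, "A", 2)
  sg <- res_atom_xyz(a, key, "SG")
  # place a partner thiol 2.05 A from SG
  partner <- build_peptide("AC", chain = "B")
  delta <- (sg + c(2.05, 0, 0)) - res_atom_xyz(partner, res_key_of(partner, "B", 2), "SG")
  partner$atoms$x <- partner$atoms$x + delta[1]
  partner$atoms$y <- partner$atoms$y + delta[2]
  partner$atoms$z <- partner$atoms$z + delta[3]
  ss <- combine_structures(a, partner)
  cands <- find_candidates(ss, modification_options("cysteine_oxidation"))
  expect_identical(nrow(cands), 0L)
  # far apart: both are candidates
  partner$atoms$x <- partner$atoms$x + 50
  free <- combine_structures(a, partner)
  expect_identical(nrow(find_candidates(
    free, modification_options("cysteine_oxidation"))), 2L)
})

test_that("racemic-choice resolves deterministically to a concrete isomer", {
  s <- build_peptide("AMA")
  res <- apply_ptm(s, res_key_of(s, "A", 2),
                   get_definition("methionine_oxidation"),
                   modification_options("methionine_oxidation"))
  expect_identical(res$entry$outcome, "modified")
  expect_true(res$entry$stereo %in% c("R", "S"))
  res_again <- apply_ptm(s, res_key_of(s, "A", 2),
                         get_definition("methionine_oxidation"),
                         modification_options("methionine_oxidation"))
  expect_identical(res$entry$stereo, res_again$entry$stereo)
})

test_that("missing side-chain atoms yield a skip, never an error", {
  s <- build_peptide("AKA")
  # truncate the lysine at CD (missing CE/NZ)
  drop <- s$atoms$serial[s$atoms$resi == 2 & s$atoms$name %in% c("CE", "NZ")]
  s2 <- ptmgraft:::.remove_atoms(s, drop)
  res <- modify_structure(s2, modification_options("acetylation"))
  expect_identical(res$report$outcome, "skipped_missing_atoms")
})

test_that("reports serialize as a versioned sidecar", {
  res <- modify_structure(build_peptide("KAK"),
                          modification_options("mda_adduct"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report(res$report, f)
  lines <- readLines(f)
  expect_match(lines[1], "report v1")
  tab <- utils::read.delim(f, comment.char = "#")
  expect_identical(nrow(tab), nrow(res$report))
})
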