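test_that("PDB write/read round trip is the identity on the core fields", {
  s <- build_peptide("AKAYC", "helix")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  s2 <- read_pdb(f)
  expect_identical(nrow(s2$atoms), nrow(s$atoms))
  expect_identical(s2$atoms$name, s$atoms$name)
  expect_identical(s2$atoms$resn, s$atoms$resn)
  expect_identical(s2$atoms$chain, s$atoms$chain)
  expect_identical(s2$atoms$resi, s$atoms$resi)
  expect_identical(s2$atoms$element, s$atoms$element)
  expect_lt(max(abs(s2$atoms$x - s$atoms$x), abs(s2$atoms$y - s$atoms$y),
                abs(s2$atoms$z - s$atoms$z)), 0.001)
  # idempotent serialization: second write is byte-identical
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s2, f2)
  s3 <- read_pdb(f2)
  f3 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s3, f3)
  expect_identical(readLines(f2), readLines(f3))
})

test_that("fixed-point coordinate formatting rounds to three decimals", {
  s <- build_peptide("A")
  s$atoms$x[1] <- 12.3456
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  expect_match(readLines(f)[1], "  12.346", fixed = TRUE)
})

test_that("read_pdb rejects empty and malformed input with useful errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("HEADER    TEST", f)
  expect_error(read_pdb(f), "no atoms")
  writeLines(c("ATOM      1  CA  ALA A   1      xxx.000   0.000   0.000"), f)
  expect_error(read_pdb(f), "line 1")
  expect_error(read_pdb(file.path(tempdir(), "does-not-exist.pdb")),
               "not found")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.30  0.00           C",
    "ATOM      3  CA BALA A   1       1.500   0.100   0.000  0.70  0.00           C",
    "ATOM      4  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C"),
    f)
  s <- read_pdb(f)
  ca <- s$atoms[s$atoms$name == "CA", ]
  expect_identical(nrow(ca), 1L)
  expect_equal(ca$x, 1.5)
  expect_identical(ca$altloc, "B")
})

test_that("modified residues serialize as HETATM with product names and REMARKs", {
  s <- build_peptide("AYA")
  res <- modify_structure(s, modification_options("nitration"))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(res$structure, f)
  lines <- readLines(f)
  expect_true(any(grepl("^HETATM.*NIY", lines)))
  expect_true(any(grepl("^REMARK 999 PTM nitration", lines)))
  # read-back preserves the rename and provenance
  s2 <- read_pdb(f)
  expect_true("NIY" %in% s2$atoms$resn)
  expect_true(any(grepl("nitration", s2$remarks)))
})

test_that("atom names longer than four characters are rejected on write", {
  s <- build_peptide("A")
  s$atoms$name[5] <- "TOOLONG"
  expect_error(write_pdb(s, withr::local_tempfile()), "4 characters")
})

test_that("peptide bonds are only inferred below the 2.0 A C-N distance", {
  s <- build_peptide("AA")
  rt <- residue_table(s)
  c1 <- ptmgraft:::.res_atom_serial(s, rt$key[1], "C")
  n2 <- ptmgraft:::.res_atom_serial(s, rt$key[2], "N")
  has_bond <- function(st, a, b)
    any((st$bonds[, 1] == min(a, b)) & (st$bonds[, 2] == max(a, b)))
  expect_true(has_bond(s, c1, n2))
  # pull the second residue away: link must vanish
  i <- paste(s$atoms$chain, s$atoms$resi, sep = "|") == "A|2"
  s$atoms$x[i] <- s$atoms$x[i] + 50
  s$bonds <- ptmgraft:::infer_bonds(s)
  expect_false(has_bond(s, c1, n2))
})

test_that("selection grammar matches a brute-force set-algebra oracle", {
  s <- build_peptide("KAKYK")
  at <- s$atoms
  expect_setequal(select_atoms(s, "resn LYS and name NZ"),
                  at$serial[at$resn == "LYS" & at$name == "NZ"])
  expect_length(select_atoms(s, "resn LYS and name NZ"), 3)
  expect_length(select_atoms(s, "chain Z"), 0)
  oracle <- at$serial[at$resi %in% 1:3 & at$name != "CA"]
  expect_setequal(select_atoms(s, "resi 1-3 and not name CA"), oracle)
  # algebra properties: intersection and complement
  A <- "resn LYS"; B <- "(name CA or name CB)"
  expect_setequal(select_atoms(s, paste(A, "and", B)),
                  intersect(select_atoms(s, A), select_atoms(s, B)))
  expect_setequal(select_atoms(s, paste("not", A)),
                  setdiff(at$serial, select_atoms(s, A)))
  expect_setequal(select_atoms(s, sprintf("not (%s or %s)", A, B)),
                  setdiff(at$serial, union(select_atoms(s, A),
                                           select_atoms(s, B))))
  expect_error(select_atoms(s, "resn"), "needs a value")
  expect_error(select_atoms(s, "bogus LYS"), "unexpected token")
  expect_error(select_atoms(s, "(resn LYS"), "missing ')'")
})
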