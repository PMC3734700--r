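test_that("toy-site PDB round-trips through read_pdb/write_pdb", {
  s <- toy_site(seed = 1)
  expect_equal(n_atoms(s), attr(s, "manifest")$n_atoms)

  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, tmp)
  s2 <- read_pdb(tmp)

  expect_equal(n_atoms(s2), n_atoms(s))
  expect_equal(s2$atoms$element, s$atoms$element)
  expect_equal(s2$atoms$name, s$atoms$name)
  expect_equal(res_key(s2$atoms$chain, s2$atoms$resnum, s2$atoms$icode),
               res_key(s$atoms$chain, s$atoms$resnum, s$atoms$icode))
  # coordinates identical to PDB precision (3 decimals)
  expect_equal(s2$atoms$x, round(s$atoms$x, 3), tolerance = 1e-12)
  expect_equal(s2$atoms$y, round(s$atoms$y, 3), tolerance = 1e-12)
  expect_equal(s2$atoms$z, round(s$atoms$z, 3), tolerance = 1e-12)
  # parse is not silently lossy
  expect_equal(attr(s2, "n_records"), n_atoms(s2) + attr(s2, "n_skipped"))
})

test_that("frozen and cap flags round-trip via REMARK records", {
  m <- toy_model(hydrogens = FALSE)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m$structure, tmp)
  s2 <- read_pdb(tmp)
  expect_equal(s2$atoms$is_frozen, m$structure$atoms$is_frozen)
  expect_equal(s2$atoms$is_cap, m$structure$atoms$is_cap)
  expect_gt(sum(s2$atoms$is_cap), 0)
})

test_that("minimal one-atom PDB parses to 1 residue / 1 atom", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  minimal_pdb(tmp)
  s <- read_pdb(tmp)
  expect_equal(n_atoms(s), 1L)
  expect_equal(length(residue_keys(s)), 1L)
  expect_equal(s$atoms$element, "C")
  expect_equal(c(s$atoms$x, s$atoms$y, s$atoms$z), c(1, 2, 3))
})

test_that("alternate locations resolve to highest occupancy, ties to first", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AGLY A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BGLY A   1       8.000   0.000   0.000  0.50  0.00           C",
    "END"), tmp)
  s <- read_pdb(tmp)
  expect_equal(n_atoms(s), 2L)
  expect_equal(attr(s, "n_skipped"), 2L)
  expect_equal(s$atoms$x[s$atoms$name == "CA"], 9)  # higher occupancy wins
  expect_equal(s$atoms$x[s$atoms$name == "CB"], 1)  # tie -> first listed
})

test_that("PDB reader errors name the offending line; writer rejects bad input", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  GLY A   1       bad     0.000   0.000  1.00  0.00           C",
    "END"), tmp)
  expect_error(read_pdb(tmp), "line 2")
  writeLines("REMARK nothing here", tmp)
  expect_error(read_pdb(tmp), "empty structure")
  empty <- new_structure(toy_site()$atoms[0, ])
  expect_error(write_pdb(empty, tmp), "empty")
  expect_error(read_pdb(file.path(tempdir(), "no-such-file.pdb")), "not found")
})

test_that("XYZ round-trip preserves positions to 6 decimals", {
  s <- toy_site(seed = 3)
  tmp <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(s, tmp)
  lines <- readLines(tmp)
  expect_equal(as.integer(lines[1]), n_atoms(s))
  s2 <- read_xyz(tmp)
  expect_equal(n_atoms(s2), n_atoms(s))
  expect_equal(s2$atoms$x, s$atoms$x, tolerance = 1e-6)
  expect_equal(s2$atoms$z, s$atoms$z, tolerance = 1e-6)
  # 1-atom structure -> 3-line file
  one <- new_structure(s$atoms[1, , drop = FALSE])
  write_xyz(one, tmp)
  expect_length(readLines(tmp), 3L)
})

test_that("structure invariants are enforced", {
  a <- toy_site()$atoms
  a$serial[2] <- a$serial[1]
  expect_error(new_structure(a), "serial")
  b <- toy_site()$atoms
  b$element[1] <- "XX"
  expect_error(new_structure(b), "element")
  d <- toy_site()$atoms
  d$x[1] <- NaN
  expect_error(new_structure(d), "finite")
  e <- toy_site()$atoms
  e$is_cap[1] <- TRUE  # first atom is not H
  expect_error(new_structure(e), "cap")
})
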