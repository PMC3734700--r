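test_that("config parser: sections, repeated keys, comments, bad lines", {
  tmp <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# a comment", "[recipe]", "residues = A:1 A:2",
               "truncation = A:1 CB CA", "truncation = A:2 CB CA  # inline",
               "[run]", "temperature = 300"), tmp)
  cfg <- parse_config(tmp)
  expect_length(cfg$recipe$truncation, 2L)
  expect_equal(cfg$run$temperature, "300")
  writeLines("just some words", tmp)
  expect_error(parse_config(tmp), "unparsable")
})

test_that("toy site generation is deterministic and self-consistent", {
  d <- withr::local_tempdir()
  p1 <- file.path(d, "a.pdb"); p2 <- file.path(d, "b.pdb")
  s1 <- generate_toy_site(toy_site_params(seed = 1), path = p1)
  s2 <- generate_toy_site(toy_site_params(seed = 1), path = p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical

  mf <- attr(s1, "manifest")
  expect_equal(mf$n_atoms, n_atoms(read_pdb(p1)))
  pos <- function(serial) {
    as.numeric(s1$atoms[s1$atoms$serial == serial, c("x", "y", "z")])
  }
  # water O sits within H-bond range of the base carboxylate O
  expect_lt(sqrt(sum((pos(mf$probes$water_O) - pos(mf$probes$base_OD1))^2)), 3.2)
  # acid OD2 within H-bond range of the epoxide O
  expect_lt(sqrt(sum((pos(mf$probes$acid_OD2) - pos(mf$probes$epoxide_O))^2)), 3.2)
  # different seeds differ
  s3 <- generate_toy_site(toy_site_params(seed = 2))
  expect_false(identical(s1$atoms$x, s3$atoms$x))
})

test_that("full pipeline reproduces the bundled tables and is deterministic", {
  d <- withr::local_tempdir()
  res <- example_run(d, seed = 1)
  expect_equal(res$barriers$delta_delta,
               c(-0.1, -1.2, -0.4, -1.0, 1.4, 3.6, 3.4), tolerance = 1e-9)
  expect_true(all(res$selectivity$agree))
  expect_true(file.exists(file.path(d, "out", "model_S3.pdb")))
  expect_true(file.exists(file.path(d, "out", "jobs.tsv")))

  # outputs carry the config hash and seed
  hdr <- readLines(file.path(d, "out", "barriers.tsv"), n = 1)
  expect_match(hdr, "config_hash=")
  expect_match(hdr, "seed=1")

  # byte-identical rerun
  d2 <- withr::local_tempdir()
  res2 <- example_run(d2, seed = 1)
  for (f in list.files(file.path(d, "out"))) {
    expect_identical(readLines(file.path(d2, "out", f)),
                     readLines(file.path(d, "out", f)),
                     label = paste("rerun of", f))
  }
})

test_that("pipeline with zero variants yields a WT-only report", {
  d <- withr::local_tempdir()
  cfg_path <- write_example_config(file.path(d, "run.cfg"))
  lines <- readLines(cfg_path)
  writeLines(lines[!grepl("^variant ", lines)], cfg_path)
  res <- suppressMessages(run_pipeline(cfg_path, file.path(d, "out"), seed = 1))
  expect_equal(res$barriers$variant, "WT")
  expect_equal(nrow(res$selectivity), 1L)
})

test_that("pipeline failures name the stage and the offending item", {
  d <- withr::local_tempdir()
  cfg_path <- write_example_config(file.path(d, "run.cfg"))
  lines <- readLines(cfg_path)
  lines <- sub("^results = .*$", "results = /no/such/table.tsv", lines)
  writeLines(lines, cfg_path)
  expect_error(
    suppressMessages(run_pipeline(cfg_path, file.path(d, "out"), seed = 1)),
    "stage 'collect'")
})

test_that("toy-engine pipeline runs end to end (single-point smoke mode)", {
  d <- withr::local_tempdir()
  cfg_path <- write_example_config(file.path(d, "run.cfg"))
  lines <- readLines(cfg_path)
  lines <- sub("^type = lookup$", "type = toy", lines)
  lines <- lines[!grepl("^variant ", lines)]
  writeLines(lines, cfg_path)
  res <- suppressWarnings(suppressMessages(
    run_pipeline(cfg_path, file.path(d, "out"), seed = 1)))
  # same geometry at every point: barriers are exactly zero
  expect_equal(res$barriers$delta_delta, 0, tolerance = 1e-9)
})

test_that("CLI verbs: make-fixture and staged runs", {
  d <- withr::local_tempdir()
  qmclust_cli(c("make-fixture", "--seed", "4", "--out", d))
  expect_true(file.exists(file.path(d, "toy_site.pdb")))
  expect_true(file.exists(file.path(d, "toy_site.pdb.manifest")))

  cfg_path <- write_example_config(file.path(d, "run.cfg"))
  out <- file.path(d, "cli-out")
  suppressMessages(suppressWarnings(
    qmclust_cli(c("jobs", "--config", cfg_path, "--out", out, "--seed", "1"))))
  expect_true(file.exists(file.path(out, "jobs.tsv")))
  expect_false(file.exists(file.path(out, "barriers.tsv")))
  jobs <- utils::read.table(file.path(out, "jobs.tsv"), header = TRUE,
                            comment.char = "#", sep = "\t")
  expect_equal(nrow(jobs), 21L)  # 7 models x 3 points

  expect_error(qmclust_cli(character(0)), "usage")
  expect_error(qmclust_cli(c("frobnicate", "--config", cfg_path)), "unknown subcommand")
})
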