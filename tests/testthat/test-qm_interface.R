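test_that("build_job copies frozen flags and yields deterministic ids", {
  m <- toy_model(hydrogens = FALSE)
  j1 <- build_job(m, task = "saddle-search", point = "TS_C1")
  expect_setequal(j1$frozen,
                  m$structure$atoms$serial[m$structure$atoms$is_frozen])
  j2 <- build_job(m, task = "saddle-search", point = "TS_C1")
  expect_identical(j1$job_id, j2$job_id)

  m2 <- m; m2$variant <- "R1"
  expect_false(build_job(m2, task = "saddle-search", point = "TS_C1")$job_id ==
                 j1$job_id)
  expect_equal(j1$charge, -2L)
})

test_that("parse_results_table reads the bundled 21-row fixture", {
  path <- system.file("extdata", "table1_results.tsv", package = "qmclust")
  res <- parse_results_table(path)
  expect_length(res, 21L)
  expect_true(all(vapply(res, function(r) r$converged, logical(1))))
  ids <- vapply(res, function(r) r$job_id, character(1))
  expect_true("WT/TS_C1/saddle-search/combined" %in% ids)
})

test_that("results-table validation: missing column, duplicate id, unconverged row", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("job_id\telectronic_energy\tzpe",
               "a\t1.0\t0.1"), tmp)
  expect_error(parse_results_table(tmp), "missing column")

  writeLines(c("job_id\telectronic_energy\tzpe\tsolvation\tdispersion\tconverged\tn_imag",
               "a\t1.0\t0.1\t0\t0\tTRUE\t0",
               "a\t2.0\t0.1\t0\t0\tTRUE\t0"), tmp)
  expect_error(parse_results_table(tmp), "duplicate")

  writeLines(c("job_id\telectronic_energy\tzpe\tsolvation\tdispersion\tconverged\tn_imag",
               "a\t1.0\t0.1\t0\t0\tFALSE\t0"), tmp)
  res <- parse_results_table(tmp)
  expect_length(res, 1L)
  expect_false(res[[1]]$converged)
})

test_that("lookup engine replays the table verbatim and is pure", {
  eng <- lookup_engine(system.file("extdata", "table1_results.tsv",
                                   package = "qmclust"))
  m <- toy_model(hydrogens = FALSE)
  spec <- build_job(m, task = "saddle-search", level = "combined",
                    point = "TS_C1")
  r1 <- run_engine(spec, eng)
  expect_equal(r1$electronic_energy, 4.4)
  expect_equal(r1$zpe, 1.6)
  expect_equal(r1$n_imag, 1L)
  expect_identical(run_engine(spec, eng), r1)

  spec$job_id <- "WT/nonsense/minimize/combined"
  expect_error(run_engine(spec, eng), "WT/nonsense/minimize/combined")
})

test_that("toy engine single-point matches the closed form on two atoms", {
  # two carbons at their reference bond length: harmonic term vanishes and
  # only the soft repulsion A * exp(-r / rho) remains
  a <- data.frame(serial = 1:2, name = c("C1", "C2"), element = "C",
                  resname = "UNK", chain = "X", resnum = 1L, icode = "",
                  x = c(0, 1.52), y = 0, z = 0)
  m <- structure(list(structure = new_structure(a),
                      recipe = cluster_recipe("X:1"), variant = "T",
                      report = list()), class = "ClusterModel")
  r <- run_engine(build_job(m, task = "single-point", point = "p"), toy_engine())
  expect_equal(r$electronic_energy, 500 * exp(-1.52 / 0.4), tolerance = 1e-12)

  # stretched bond adds the harmonic term
  a$x[2] <- 1.80
  m$structure <- new_structure(a)
  r2 <- run_engine(build_job(m, task = "single-point", point = "p"), toy_engine())
  expect_equal(r2$electronic_energy,
               300 * (1.80 - 1.52)^2 + 500 * exp(-1.80 / 0.4),
               tolerance = 1e-12)
})

test_that("toy engine energy is invariant under rigid motion", {
  m <- toy_model(hydrogens = FALSE)
  e0 <- run_engine(build_job(m, task = "single-point", point = "p"),
                   toy_engine())$electronic_energy
  R <- rand_rotation(7)
  m2 <- m
  xyz <- as.matrix(m$structure$atoms[, c("x", "y", "z")]) %*% t(R)
  m2$structure$atoms$x <- xyz[, 1] + 3.2
  m2$structure$atoms$y <- xyz[, 2] - 1.1
  m2$structure$atoms$z <- xyz[, 3] + 0.7
  e1 <- run_engine(build_job(m2, task = "single-point", point = "p"),
                   toy_engine())$electronic_energy
  expect_equal(e1, e0, tolerance = 1e-8)
})

test_that("toy engine minimize descends and never displaces frozen atoms", {
  m <- toy_model(hydrogens = FALSE)
  set.seed(11)
  pert <- m
  free <- !pert$structure$atoms$is_frozen
  pert$structure$atoms$x[free] <- pert$structure$atoms$x[free] +
    rnorm(sum(free), 0, 0.05)
  e_start <- run_engine(build_job(pert, task = "single-point", point = "p"),
                        toy_engine())$electronic_energy
  r <- run_engine(build_job(pert, task = "minimize", point = "ES"), toy_engine())
  expect_true(r$converged)
  expect_lte(r$electronic_energy, e_start)
  frozen <- pert$structure$atoms$is_frozen
  expect_identical(r$geometry$atoms[frozen, c("x", "y", "z")],
                   pert$structure$atoms[frozen, c("x", "y", "z")],
                   ignore_attr = TRUE)
  # saddle searches are out of contract
  expect_error(run_engine(build_job(pert, task = "saddle-search", point = "TS"),
                          toy_engine()), "saddle")
})
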