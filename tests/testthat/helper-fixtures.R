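# Shared fixtures, built in code at test time.

toy_site <- function(seed = 1, n_residues = 5) {
  generate_toy_site(toy_site_params(seed = seed, n_residues = n_residues))
}

# recipe matching the default 5-residue toy site
toy_recipe <- function(truncations = list(
                         truncation_rule("A:101", "CB", "CA", "alpha"),
                         truncation_rule("A:132", "CB", "CA", "alpha")),
                       frozen = NULL) {
  cluster_recipe(
    residues = c("A:32", "A:74", "A:80", "A:101", "A:132", "W:201"),
    truncations = truncations, ligand = "L:1",
    charge = -2L, frozen = frozen
  )
}

toy_protonation <- list("A:101" = "neutral", "A:132" = "anionic")

toy_model <- function(seed = 1, hydrogens = TRUE, n_residues = 5) {
  s <- generate_toy_site(toy_site_params(seed = seed, n_residues = n_residues))
  m <- build_cluster(s, toy_recipe())
  if (hydrogens) m <- add_hydrogens(m, toy_protonation)
  m
}

# a single-ATOM minimal PDB text
minimal_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), path)
  path
}

# profile with prescribed total energies (components split arbitrarily but
# consistently so total_energy reassembles them)
profile_from_totals <- function(variant, es, ts_c1, ts_c2) {
  mk <- function(label, total, n_imag) {
    r <- qm_result(paste0(variant, "/", label), total - 1.5 + 2.0 - 0.5,
                   zpe = 1.5, solvation = -2.0, dispersion = 0.5,
                   n_imag = n_imag)
    stationary_point(label, r)
  }
  reaction_profile(variant, list(mk("ES", es, 0L), mk("TS_C1", ts_c1, 1L),
                                 mk("TS_C2", ts_c2, 1L)))
}

# deterministic random rotation matrix
rand_rotation <- function(seed) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3, 3)
  q <- qr(M)
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# independent RMSD oracle: minimize over Euler angles by multi-start
# Nelder-Mead after centroid removal (never touches the Kabsch path)
rmsd_oracle <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  euler <- function(p) {
    ca <- cos(p[1]); sa <- sin(p[1])
    cb <- cos(p[2]); sb <- sin(p[2])
    cg <- cos(p[3]); sg <- sin(p[3])
    Rz1 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
    Rz2 <- matrix(c(cg, sg, 0, -sg, cg, 0, 0, 0, 1), 3, 3)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(p) sqrt(mean(rowSums((Xc %*% t(euler(p)) - Yc)^2)))
  best <- Inf
  starts <- expand.grid(a = c(0, pi / 2, pi, 3 * pi / 2),
                        b = c(0, pi / 2, pi), g = c(0, pi))
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[i, ]), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-16, maxit = 5000))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-16, maxit = 5000))
    best <- min(best, fit$value)
  }
  best
}

atom_pos <- function(s, key, name) {
  r <- s$atoms[paste(s$atoms$chain, s$atoms$resnum, sep = ":") == key &
                 s$atoms$name == name, ]
  c(r$x, r$y, r$z)
}

example_run <- function(dir, seed = 1) {
  cfg <- write_example_config(file.path(dir, "run.cfg"), seed = seed)
  suppressMessages(suppressWarnings(
    run_pipeline(cfg, file.path(dir, "out"), seed = seed)))
}
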