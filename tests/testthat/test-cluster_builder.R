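test_that("build_cluster keeps recipe residues, caps every cut, freezes caps", {
  s <- toy_site(seed = 1)
  m <- build_cluster(s, toy_recipe())
  a <- m$structure$atoms

  # kept heavy atoms by hand: the two ASPs lose N,CA,C,O (4 atoms each)
  n_expected <- attr(s, "manifest")$n_atoms - 2 * 4 + 2  # + 2 caps
  expect_equal(n_atoms(m$structure), n_expected)
  expect_equal(sum(a$is_cap), 2L)
  expect_true(all(a$is_frozen[a$is_cap]))
  # default frozen set = caps + attachment atoms
  expect_equal(sum(a$is_frozen), 4L)
  akeys <- res_key(a$chain, a$resnum, a$icode)
  expect_true(all(a$name[akeys == "A:101" & !a$is_cap] %in%
                    c("CB", "CG", "OD1", "OD2")))
  # caps carry a distinguishable name prefix and are hydrogens
  expect_true(all(grepl("^HL", a$name[a$is_cap])))
  # ligand flagged hetero
  expect_true(all(a$is_het[akeys == "L:1"]))
})

test_that("zero truncations give the untruncated selection; errors are named", {
  s <- toy_site(seed = 1)
  m0 <- build_cluster(s, toy_recipe(truncations = list()))
  expect_equal(sum(m0$structure$atoms$is_cap), 0L)
  keep <- res_key(s$atoms$chain, s$atoms$resnum, s$atoms$icode) %in%
    c(toy_recipe()$residues, "L:1")
  expect_equal(n_atoms(m0$structure), sum(keep))

  bad <- cluster_recipe(residues = c("A:101", "B:999"), ligand = "L:1")
  expect_error(build_cluster(s, bad), "B:999")
  bad2 <- toy_recipe(truncations = list(truncation_rule("A:101", "CB", "XX")))
  expect_error(build_cluster(s, bad2), "XX")
  # implausibly long "bond" is rejected
  bad3 <- toy_recipe(truncations = list(truncation_rule("A:101", "OD1", "N")))
  expect_error(build_cluster(s, bad3), "not a plausible bond")
})

test_that("explicit frozen selectors override the attachment default", {
  s <- toy_site(seed = 1)
  m <- build_cluster(s, toy_recipe(frozen = c("A:74:CA", "A:80:CA")))
  a <- m$structure$atoms
  expect_true(all(a$is_frozen[a$is_cap]))  # caps always frozen
  frozen_names <- paste(res_key(a$chain, a$resnum, a$icode), a$name)[a$is_frozen]
  expect_true(all(c("A:74 CA", "A:80 CA") %in% frozen_names))
  expect_equal(sum(a$is_frozen), 4L)  # 2 caps + 2 selectors
})

test_that("place_cap_hydrogen constructs a collinear cap at the bond length", {
  h <- place_cap_hydrogen(c(0, 0, 0), c(0, 0, 1.5), 1.10)
  expect_equal(c(h$x, h$y, h$z), c(0, 0, 1.10), tolerance = 1e-12)
  expect_true(h$is_cap && h$is_frozen)
  expect_equal(h$element, "H")

  set.seed(42)
  for (i in 1:20) {
    kept <- rnorm(3); removed <- rnorm(3)
    if (sqrt(sum((kept - removed)^2)) < 1e-3) next
    bl <- runif(1, 0.9, 1.3)
    h <- place_cap_hydrogen(kept, removed, bl)
    pos <- c(h$x, h$y, h$z)
    expect_equal(sqrt(sum((pos - kept)^2)), bl, tolerance = 1e-10)
    cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])
    expect_lt(sqrt(sum(cr(pos - kept, removed - kept)^2)), 1e-10)
  }
  expect_error(place_cap_hydrogen(c(0, 0, 0), c(0, 0, 0)), "coincident")
})

test_that("add_hydrogens places template hydrogens and is idempotent", {
  m <- toy_model(hydrogens = FALSE)
  mh <- add_hydrogens(m, toy_protonation)
  a <- mh$structure$atoms
  akeys <- res_key(a$chain, a$resnum, a$icode)
  is_h <- a$element == "H" & !a$is_cap

  # water: 2 H at ~0.96 A and ~104.5 deg
  w <- a[akeys == "W:201", ]
  expect_equal(sum(w$element == "H"), 2L)
  o <- as.numeric(w[w$name == "O", c("x", "y", "z")])
  h1 <- as.numeric(w[w$element == "H", c("x", "y", "z")][1, ])
  h2 <- as.numeric(w[w$element == "H", c("x", "y", "z")][2, ])
  expect_equal(sqrt(sum((h1 - o)^2)), 0.96, tolerance = 1e-6)
  expect_equal(vec_angle(h1, o, h2), 104.5, tolerance = 1e-3)

  # hand template count for the whole model:
  # LEU 74: N1 CA1 CB2 CG1 CD1x3 CD2x3 = 11 ; ILE 80: 1+1+1+2+3+3 = 11
  # MET 32: 1+1+2+2+3 = 9 ; ASP 101 neutral fragment: CB2 + OD2-H = 3
  # ASP 132 anionic fragment: CB2 = 2 ; water 2 ; EPX ligand 8
  expect_equal(sum(is_h), 11 + 11 + 9 + 3 + 2 + 2 + 8)

  # neutral acid has the OD2 proton, the anionic base does not
  expect_true("HD2" %in% a$name[akeys == "A:101"])
  expect_false(any(grepl("^HD2", a$name[akeys == "A:132"])))

  # idempotent on a fully protonated model
  mh2 <- add_hydrogens(mh, toy_protonation)
  expect_equal(n_atoms(mh2$structure), n_atoms(mh$structure))

  # undeclared titratable residue is an error listing the culprit
  expect_error(add_hydrogens(m, list("A:101" = "neutral")), "A:132")
})

test_that("added hydrogens are frozen only on cap attachments", {
  m <- toy_model(hydrogens = FALSE)
  mh <- add_hydrogens(m, toy_protonation)
  a <- mh$structure$atoms
  akeys <- res_key(a$chain, a$resnum, a$icode)
  added_h <- a$element == "H" & !a$is_cap
  # the frozen cap-attachment CB atoms of the truncated acids carry frozen H
  on_attachment <- added_h & akeys %in% c("A:101", "A:132") & grepl("^HB", a$name)
  expect_true(all(a$is_frozen[on_attachment]))
  expect_false(any(a$is_frozen[added_h & !on_attachment]))
})

test_that("mutation bookkeeping: self-mutation, Ile->Val, frozen & locality", {
  m <- toy_model()
  expect_identical(mutate_residue(m, "A:74", "LEU", "LEU"), m)
  expect_error(mutate_residue(m, "A:74", "ILE", "VAL"), "mismatch")

  mv <- mutate_residue(m, "A:80", "ILE", "VAL")
  heavy <- function(x) sum(x$structure$atoms$element != "H")
  expect_equal(heavy(mv), heavy(m) - 1L)  # CD1 removed
  a <- mv$structure$atoms
  akeys <- res_key(a$chain, a$resnum, a$icode)
  expect_setequal(a$name[akeys == "A:80" & a$element != "H"],
                  c("N", "CA", "C", "O", "CB", "CG1", "CG2"))
  expect_equal(unique(a$resname[akeys == "A:80"]), "VAL")

  # locality: atoms outside the mutated residue are bitwise unchanged
  b <- m$structure$atoms
  bkeys <- res_key(b$chain, b$resnum, b$icode)
  expect_identical(a[akeys != "A:80", names(a) != "serial"],
                   b[bkeys != "A:80", names(b) != "serial"],
                   ignore_attr = TRUE)

  # frozen atoms never move across builder operations
  frozen_before <- b[b$is_frozen, c("name", "x", "y", "z")]
  frozen_after <- a[a$is_frozen, c("name", "x", "y", "z")]
  expect_identical(frozen_after, frozen_before, ignore_attr = TRUE)
})

test_that("chi1 is inherited from the parent side chain", {
  m <- toy_model()
  g <- function(mm, key, nm) atom_pos(mm$structure, key, nm)
  tors <- function(mm, key, gamma) {
    p <- vapply(c("N", "CA", "CB", gamma), function(nm) g(mm, key, nm),
                numeric(3))
    qmclust:::torsion_deg(p[, 1], p[, 2], p[, 3], p[, 4])
  }
  chi1_parent <- tors(m, "A:74", "CG")
  mv <- mutate_residue(m, "A:74", "LEU", "ILE")
  angdiff <- (tors(mv, "A:74", "CG1") - chi1_parent + 180) %% 360 - 180
  expect_equal(angdiff, 0, tolerance = 1e-6)
})

test_that("variants: R1 analogue differs at 2 residues, S2 adds exactly one", {
  m <- toy_model()
  r1 <- variant_spec("R1", list(
    list(key = "A:74", from = "LEU", to = "ILE"),
    list(key = "A:80", from = "ILE", to = "CYS", protonation = "thiol")))
  mr1 <- apply_variant(m, r1)
  expect_equal(mr1$variant, "R1")

  changed_residues <- function(x, y) {
    ax <- x$structure$atoms; ay <- y$structure$atoms
    kx <- res_key(ax$chain, ax$resnum, ax$icode)
    ky <- res_key(ay$chain, ay$resnum, ay$icode)
    sig <- function(a, k) vapply(split(paste(a$name, round(a$x, 6), round(a$y, 6)),
                                       k), paste, character(1), collapse = "|")
    sx <- sig(ax, kx); sy <- sig(ay, ky)
    keys <- union(names(sx), names(sy))
    keys[vapply(keys, function(k) !identical(sx[k], sy[k]), logical(1))]
  }
  expect_setequal(changed_residues(mr1, m), c("A:74", "A:80"))

  # empty variant is the identity
  m0 <- apply_variant(m, variant_spec("null", list()))
  expect_equal(m0$structure$atoms, m$structure$atoms)

  # S2 = S1 + one extra mutation on a 7-residue site
  m7 <- add_hydrogens(build_cluster(toy_site(n_residues = 7), cluster_recipe(
    residues = c("A:32", "A:74", "A:80", "A:101", "A:114", "A:116", "A:132", "W:201"),
    truncations = list(truncation_rule("A:101", "CB", "CA"),
                       truncation_rule("A:132", "CB", "CA")),
    ligand = "L:1", charge = -2L)), toy_protonation)
  s1 <- apply_variant(m7, variant_spec("S1", list(
    list(key = "A:114", from = "LEU", to = "CYS", protonation = "thiol"),
    list(key = "A:116", from = "ILE", to = "VAL"))))
  s2 <- apply_variant(m7, variant_spec("S2", list(
    list(key = "A:114", from = "LEU", to = "CYS", protonation = "thiol"),
    list(key = "A:116", from = "ILE", to = "VAL"),
    list(key = "A:80", from = "ILE", to = "PHE"))))
  expect_setequal(changed_residues(s2, s1), "A:80")
})

test_that("non-adjacent mutations commute", {
  m <- toy_model()
  ab <- mutate_residue(mutate_residue(m, "A:74", "LEU", "ILE"),
                       "A:80", "ILE", "VAL")
  ba <- mutate_residue(mutate_residue(m, "A:80", "ILE", "VAL"),
                       "A:74", "LEU", "ILE")
  sig <- function(x) {
    a <- x$structure$atoms
    sort(paste(res_key(a$chain, a$resnum, a$icode), a$name,
               round(a$x, 9), round(a$y, 9), round(a$z, 9)))
  }
  expect_identical(sig(ab), sig(ba))
})

test_that("mutating to a titratable residue demands a protonation state", {
  m <- toy_model()
  expect_error(mutate_residue(m, "A:80", "ILE", "CYS"), "protonation")
  ok <- mutate_residue(m, "A:80", "ILE", "CYS", protonation = "thiol")
  a <- ok$structure$atoms
  akeys <- res_key(a$chain, a$resnum, a$icode)
  expect_true("SG" %in% a$name[akeys == "A:80"])
  expect_equal(sum(a$element == "H" & akeys == "A:80" &
                     grepl("^HG", a$name)), 1L)  # thiol H present
})

test_that("steric clashes warn but do not abort", {
  m <- toy_model()
  # force the new side chain into the pocket with a hostile chi1
  expect_warning(
    mutate_residue(m, "A:74", "LEU", "PHE", chi1 = -90),
    "clash")
})
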