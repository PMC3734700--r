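#' Parameters for the synthetic toy active site
#'
#' The generator stands in, at desk scale, for a crystal structure of an
#' epoxide-hydrolase-like active site. It emulates the catalytic motif — an
#' epoxide-bearing ligand, an acid residue hydrogen-bonded to the epoxide
#' oxygen, a base residue with the nucleophilic water, and hydrophobic pocket
#' residues — not real protein geometry: residues sit on an idealized ring
#' with template side chains plus a small Gaussian jitter.
#'
#' @param seed RNG seed; the generator is fully deterministic given it.
#' @param n_residues number of amino-acid pocket residues (>= 2; the first
#'   two are the acid and base aspartates).
#' @param radius radial distance (Angstrom) of the hydrophobic side-chain
#'   attachment points from the ligand center.
#' @param noise Gaussian coordinate jitter, Angstrom (applied to pocket
#'   residues only, so the constructed hydrogen-bond distances are exact).
#' @export
toy_site_params <- function(seed = 1L, n_residues = 5L, radius = 5.2,
                            noise = 0.02) {
  if (n_residues < 2) stop("need at least the acid and base residues")
  structure(list(seed = as.integer(seed), n_residues = as.integer(n_residues),
                 radius = radius, noise = noise), class = "toy_site_params")
}

# idealized heavy-atom residue in a local frame (CA at origin)
build_residue_local <- function(resname, chi1 = 180) {
  ca <- c(0, 0, 0)
  n <- 1.46 * c(cos(55 * pi / 180), sin(55 * pi / 180), 0)
  cc <- 1.52 * c(cos(-55 * pi / 180), sin(-55 * pi / 180), 0)
  coords <- list(N = n, CA = ca, C = cc)
  coords$O <- nerf_place(coords$N, coords$CA, coords$C, 1.23, 121, 180)
  atoms <- list(list("N", "N"), list("CA", "C"), list("C", "C"), list("O", "O"))
  if (resname != "GLY") {
    coords$CB <- nerf_place(coords$C, coords$N, coords$CA, 1.53, 110.5, -122)
    atoms <- c(atoms, list(list("CB", "C")))
    for (ta in .SIDECHAIN_TEMPLATES[[resname]]) {
      refs <- lapply(ta$refs, function(nm) coords[[nm]])
      dih <- if (is.list(ta$dihedral)) chi1 + ta$dihedral$chi else ta$dihedral
      coords[[ta$name]] <- nerf_place(refs[[1]], refs[[2]], refs[[3]],
                                      ta$bond, ta$angle, dih)
      atoms <- c(atoms, list(list(ta$name, ta$element)))
    }
  }
  data.frame(
    name = vapply(atoms, `[[`, character(1), 1),
    element = vapply(atoms, `[[`, character(1), 2),
    x = vapply(atoms, function(a) coords[[a[[1]]]][1], numeric(1)),
    y = vapply(atoms, function(a) coords[[a[[1]]]][2], numeric(1)),
    z = vapply(atoms, function(a) coords[[a[[1]]]][3], numeric(1)),
    stringsAsFactors = FALSE
  )
}

# rigidly place a local residue so atom `tip` lands at `target` with the
# tip->CA direction along +v (side chain pointing back along -v)
place_residue <- function(local, tip, target, v) {
  tp <- as.numeric(local[local$name == tip, c("x", "y", "z")])
  ca <- as.numeric(local[local$name == "CA", c("x", "y", "z")])
  R <- rotation_between(unit(ca - tp), unit(v))
  xyz <- as.matrix(local[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, tp) %*% t(R)
  xyz <- sweep(xyz, 2, target, `+`)
  local$x <- xyz[, 1]; local$y <- xyz[, 2]; local$z <- xyz[, 3]
  local
}

.POCKET_RESIDUES <- list(
  list("LEU", 74L), list("ILE", 80L), list("MET", 32L), list("LEU", 114L),
  list("ILE", 116L), list("VAL", 83L), list("LEU", 35L), list("MET", 78L)
)

#' Generate the synthetic toy active site
#'
#' Builds a deterministic, desk-scale active-site structure: a cyclopentene
#' oxide analogue (residue `EPX`, chain L) with the epoxide oxygen bridging
#' the C1/C2 carbons; an acid aspartate (A:101) whose OD2 sits exactly 2.7 A
#' from the epoxide oxygen; a base aspartate (A:132) with a water (W:201)
#' oxygen exactly 2.9 A from its OD1 (within nucleophilic-attack reach); and
#' hydrophobic pocket residues. Heavy atoms only — hydrogens are added
#' downstream, as for a crystal structure.
#'
#' The ground-truth manifest (attribute `"manifest"`, also written next to
#' the PDB as `<path>.manifest` when `path` is given) records the intended
#' atom count, residue table, perceived bond count and the probe atom
#' serials (epoxide O/C1/C2, acid OD2, base OD1, water O).
#'
#' @param params a [toy_site_params()].
#' @param path optional output PDB path.
#' @return a `Structure` with the manifest attached.
#' @export
generate_toy_site <- function(params = toy_site_params(), path = NULL) {
  set.seed(params$seed)

  # ligand: cyclopentane ring + epoxide O bridging C1-C2
  rc <- 1.5 / (2 * sin(pi / 5))
  ring_ang <- 90 + 72 * (0:4) - 36  # C1,C2 flank the +y direction
  lig <- data.frame(
    name = c(paste0("C", 1:5), "O"),
    element = c(rep("C", 5), "O"),
    x = c(rc * cos(ring_ang * pi / 180), 0),
    y = c(rc * sin(ring_ang * pi / 180), 0),
    z = c(rep(0, 5), 0), stringsAsFactors = FALSE
  )
  mid <- c(mean(lig$x[1:2]), mean(lig$y[1:2]), 0)
  h <- sqrt(1.43^2 - (1.5 / 2)^2)
  epox_o <- mid + c(0, 0, h)
  lig[6, c("x", "y", "z")] <- as.list(epox_o)
  lig$resname <- "EPX"; lig$chain <- "L"; lig$resnum <- 1L
  lig$is_het <- TRUE

  res_frames <- list()
  # acid aspartate: OD2 exactly 2.7 A from the epoxide O, outward and up
  u1 <- unit(c(0, 1, 0.35))
  asp_acid <- place_residue(build_residue_local("ASP"), "OD2",
                            epox_o + 2.7 * u1, u1)
  asp_acid$resname <- "ASP"; asp_acid$chain <- "A"; asp_acid$resnum <- 101L
  asp_acid$is_het <- FALSE
  res_frames[["A:101"]] <- asp_acid

  # base aspartate + nucleophilic water
  u2 <- unit(c(0, -1, 0.1))
  base_tip <- 5.0 * u2
  asp_base <- place_residue(build_residue_local("ASP"), "OD1", base_tip, u2)
  asp_base$resname <- "ASP"; asp_base$chain <- "A"; asp_base$resnum <- 132L
  asp_base$is_het <- FALSE
  res_frames[["A:132"]] <- asp_base
  wdir <- unit(-u2 + c(0, 0, 1.8))
  wat_o <- base_tip + 2.9 * wdir
  wat <- data.frame(name = "O", element = "O", x = wat_o[1], y = wat_o[2],
                    z = wat_o[3], resname = "HOH", chain = "W", resnum = 201L,
                    is_het = TRUE, stringsAsFactors = FALSE)

  # hydrophobic pocket residues at the remaining slots
  n_hydro <- params$n_residues - 2L
  slot_ang <- c(0, 180, 45, 135, 225, 315, 70, 250)
  zoff <- rep(c(2.0, -2.0), length.out = n_hydro)
  if (n_hydro > 0) {
    for (i in seq_len(n_hydro)) {
      spec <- .POCKET_RESIDUES[[(i - 1) %% length(.POCKET_RESIDUES) + 1]]
      ang <- slot_ang[(i - 1) %% length(slot_ang) + 1] * pi / 180
      v <- unit(c(cos(ang), sin(ang), 0))
      target <- params$radius * v + c(0, 0, zoff[i])
      r <- place_residue(build_residue_local(spec[[1]]), "CB", target, v)
      r$resname <- spec[[1]]; r$chain <- "A"
      r$resnum <- spec[[2]] + 1000L * ((i - 1) %/% length(.POCKET_RESIDUES))
      r$is_het <- FALSE
      res_frames[[res_key("A", r$resnum[1])]] <- r
    }
  }

  # hydrophobic-residue jitter (catalytic H-bond geometry stays exact)
  prot <- do.call(rbind, res_frames)
  jit <- !(prot$resnum %in% c(101L, 132L))
  if (params$noise > 0 && any(jit)) {
    nj <- sum(jit)
    prot$x[jit] <- prot$x[jit] + stats::rnorm(nj, 0, params$noise)
    prot$y[jit] <- prot$y[jit] + stats::rnorm(nj, 0, params$noise)
    prot$z[jit] <- prot$z[jit] + stats::rnorm(nj, 0, params$noise)
  }

  # order: protein by residue number, then ligand, then water
  prot <- prot[order(prot$resnum), , drop = FALSE]
  atoms <- rbind(prot, lig, wat)
  atoms$icode <- ""
  atoms$serial <- seq_len(nrow(atoms))
  atoms$x <- round(atoms$x, 3); atoms$y <- round(atoms$y, 3)
  atoms$z <- round(atoms$z, 3)  # PDB precision from the start
  s <- new_structure(atoms, title = sprintf("qmclust toy active site (seed %d)",
                                            params$seed))
  sn <- function(key, name) {
    a <- s$atoms[atom_res_keys(s) == key & s$atoms$name == name, ]
    a$serial
  }
  manifest <- list(
    seed = params$seed,
    n_atoms = n_atoms(s),
    n_bonds = nrow(detect_bonds(s)),
    residues = data.frame(key = residue_keys(s),
                          resname = s$atoms$resname[!duplicated(atom_res_keys(s))],
                          stringsAsFactors = FALSE),
    probes = list(epoxide_O = sn("L:1", "O"), C1 = sn("L:1", "C1"),
                  C2 = sn("L:1", "C2"), acid_OD2 = sn("A:101", "OD2"),
                  base_OD1 = sn("A:132", "OD1"), water_O = sn("W:201", "O"))
  )
  attr(s, "manifest") <- manifest
  if (!is.null(path)) {
    write_pdb(s, path)
    mf <- c(sprintf("seed %d", manifest$seed),
            sprintf("n_atoms %d", manifest$n_atoms),
            sprintf("n_bonds %d", manifest$n_bonds),
            vapply(names(manifest$probes),
                   function(p) sprintf("probe %s %d", p, manifest$probes[[p]]),
                   character(1)),
            sprintf("residue %s %s", manifest$residues$key, manifest$residues$resname))
    writeLines(mf, paste0(path, ".manifest"))
  }
  s
}
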