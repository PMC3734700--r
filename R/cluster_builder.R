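#' Truncation rule for a cluster recipe
#'
#' Describes one severed covalent bond: the kept atom stays in the model, the
#' removed atom (and everything connected through it within the residue) is
#' deleted and replaced by a single link hydrogen placed along the cut bond.
#'
#' @param residue_key residue key (see [res_key()]).
#' @param keep atom name kept in the model (the cap attachment atom).
#' @param remove atom name on the discarded side of the cut bond.
#' @param scheme truncation scheme tag: `"alpha"` (keep side chain from
#'   C-beta, cap at the C-alpha position), `"beta"` (keep from C-gamma) or
#'   `"backbone"` (keep a backbone segment, cap at the flanking C-alpha).
#' @export
truncation_rule <- function(residue_key, keep, remove,
                            scheme = c("alpha", "beta", "backbone")) {
  scheme <- match.arg(scheme)
  structure(list(residue_key = residue_key, keep = keep, remove = remove,
                 scheme = scheme), class = "truncation_rule")
}

#' Cluster-model recipe
#'
#' The declarative input for [build_cluster()]: which residues of the parent
#' structure enter the model, where bonds are cut, the ligand, total charge
#' and multiplicity, and (optionally) an explicit locked-atom list.
#'
#' By default the frozen set is every cap hydrogen plus its attachment heavy
#' atom — the coordinate-locking scheme that anchors the truncation points at
#' their crystallographic positions. `frozen` selectors
#' (`"<chain>:<resnum>:<atomname>"`) override the attachment-atom default;
#' cap hydrogens are always frozen.
#'
#' @param residues character vector of residue keys to include.
#' @param truncations list of [truncation_rule()] objects.
#' @param ligand residue key of the ligand (included as hetero), or NULL.
#' @param charge net model charge, integer e.
#' @param multiplicity spin multiplicity.
#' @param frozen optional character vector of atom selectors.
#' @export
cluster_recipe <- function(residues, truncations = list(), ligand = NULL,
                           charge = 0L, multiplicity = 1L, frozen = NULL) {
  if (abs(charge - round(charge)) > 1e-9) stop("charge must be an integer")
  for (tr in truncations) {
    if (!inherits(tr, "truncation_rule")) stop("truncations must be truncation_rule objects")
    if (!(tr$residue_key %in% residues)) {
      stop("truncation rule refers to a residue not in the recipe: ", tr$residue_key)
    }
  }
  structure(list(residues = residues, truncations = truncations,
                 ligand = ligand, charge = as.integer(round(charge)),
                 multiplicity = as.integer(multiplicity), frozen = frozen),
            class = "cluster_recipe")
}

# "A:101:CB" -> list(key = "A:101", name = "CB")
parse_selector <- function(sel) {
  parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
  if (length(parts) < 3) stop("bad atom selector (want chain:resnum:atom): ", sel)
  list(key = paste(parts[-length(parts)], collapse = ":"),
       name = parts[length(parts)])
}

#' Place a link (cap) hydrogen along a severed bond
#'
#' The hydrogen sits on the segment from the kept atom toward the removed
#' atom at the given bond length, so the cut bond's direction — and with the
#' locking scheme, the crystal-frame geometry of the truncation point — is
#' preserved.
#'
#' @param kept,removed positions (length-3 numeric) or single atom rows.
#' @param bond_length cap bond length in Angstrom (1.10 for C-H, 1.01 N-H).
#' @return a one-row atom data.frame with `is_cap = is_frozen = TRUE`.
#' @export
place_cap_hydrogen <- function(kept, removed, bond_length = 1.10) {
  as_pos <- function(a) if (is.data.frame(a)) c(a$x, a$y, a$z) else as.numeric(a)
  pk <- as_pos(kept); pr <- as_pos(removed)
  if (vnorm(pr - pk) < 1e-9) stop("kept and removed atoms are coincident")
  pos <- pk + bond_length * unit(pr - pk)
  tmplt <- if (is.data.frame(kept)) kept else
    data.frame(serial = NA_integer_, name = "", element = "", resname = "UNK",
               chain = "X", resnum = 1L, icode = "", x = 0, y = 0, z = 0,
               is_het = FALSE, is_frozen = FALSE, is_cap = FALSE)
  h <- tmplt[1, , drop = FALSE]
  h$name <- "HL"; h$element <- "H"
  h$x <- pos[1]; h$y <- pos[2]; h$z <- pos[3]
  h$is_cap <- TRUE; h$is_frozen <- TRUE
  rownames(h) <- NULL
  h
}

cap_bond_length <- function(element) {
  switch(toupper(element), C = 1.10, N = 1.01, O = 0.97, S = 1.34, 1.10)
}

#' Build a truncated, capped, coordinate-locked cluster model
#'
#' Retains only the recipe's residues (plus the ligand), severs each declared
#' cut bond, deletes the atoms on the removed side (the connected component
#' through the removed atom within its residue), places one cap hydrogen per
#' cut, and flags the frozen set. This is the standard cluster-approach model
#' preparation: a limited active-site region, valence-capped, with truncation
#' points fixed at their crystallographic coordinates.
#'
#' @param structure a `Structure` (e.g. from [read_pdb()]).
#' @param recipe a [cluster_recipe()].
#' @param variant variant label recorded on the model (default `"WT"`).
#' @return a `ClusterModel`: list with `structure`, `recipe`, `variant` and a
#'   build `report` (atom/cap counts, frozen serials, warnings).
#' @export
build_cluster <- function(structure, recipe, variant = "WT") {
  keys <- atom_res_keys(structure)
  wanted <- recipe$residues
  missing <- setdiff(c(wanted, recipe$ligand), unique(keys))
  if (length(missing) > 0) {
    stop("recipe residue(s) absent from structure: ", paste(missing, collapse = ", "))
  }
  sel <- keys %in% c(wanted, recipe$ligand)
  atoms <- structure$atoms[sel, , drop = FALSE]
  if (!is.null(recipe$ligand)) {
    akeys <- res_key(atoms$chain, atoms$resnum, atoms$icode)
    atoms$is_het[akeys == recipe$ligand] <- TRUE
  }
  sub <- new_structure(atoms, title = structure$title)

  caps <- list()
  attachment_serials <- integer(0)
  for (tr in recipe$truncations) {
    res <- get_residue(sub, tr$residue_key)
    kept <- res[res$name == tr$keep, , drop = FALSE]
    removed <- res[res$name == tr$remove, , drop = FALSE]
    if (nrow(kept) != 1 || nrow(removed) != 1) {
      stop(sprintf("cut-bond atoms %s-%s not found (once each) in residue %s",
                   tr$keep, tr$remove, tr$residue_key))
    }
    d <- vnorm(c(kept$x, kept$y, kept$z) - c(removed$x, removed$y, removed$z))
    if (d >= 2.0) {
      stop(sprintf("cut bond %s-%s in %s is %.2f A apart: not a plausible bond",
                   tr$keep, tr$remove, tr$residue_key, d))
    }
    # delete the connected component through the removed atom (bond
    # keep-remove severed), restricted to this residue
    res_idx <- which(atom_res_keys(sub) == tr$residue_key)
    res_s <- new_structure(sub$atoms[res_idx, , drop = FALSE])
    bonds <- detect_bonds(res_s)
    ik <- which(res_s$atoms$name == tr$keep)
    ir <- which(res_s$atoms$name == tr$remove)
    sever <- (bonds[, 1] == ik & bonds[, 2] == ir) | (bonds[, 1] == ir & bonds[, 2] == ik)
    bonds <- bonds[!sever, , drop = FALSE]
    comp <- connected_component(ir, bonds, nrow(res_s$atoms))
    if (ik %in% comp) {
      stop(sprintf("cut bond %s-%s in %s is part of a ring: cannot truncate",
                   tr$keep, tr$remove, tr$residue_key))
    }
    drop_serials <- res_s$atoms$serial[comp]
    sub$atoms <- sub$atoms[!(sub$atoms$serial %in% drop_serials), , drop = FALSE]
    cap <- place_cap_hydrogen(kept, removed, cap_bond_length(kept$element))
    attachment_serials <- c(attachment_serials, kept$serial)
    caps[[length(caps) + 1]] <- cap
  }
  if (length(caps) > 0) {
    cap_df <- do.call(rbind, caps)
    cap_df$serial <- max(sub$atoms$serial) + seq_len(nrow(cap_df))
    cap_df$name <- paste0("HL", seq_len(nrow(cap_df)))
    sub$atoms <- rbind(sub$atoms, cap_df)
  }

  # frozen set: caps always; attachments by default, or explicit selectors
  sub$atoms$is_frozen <- sub$atoms$is_cap
  if (is.null(recipe$frozen)) {
    sub$atoms$is_frozen <- sub$atoms$is_frozen | sub$atoms$serial %in% attachment_serials
  } else {
    akeys <- atom_res_keys(sub)
    for (selr in recipe$frozen) {
      p <- parse_selector(selr)
      hit <- akeys == p$key & sub$atoms$name == p$name
      if (!any(hit)) stop("frozen-atom selector matches nothing: ", selr)
      sub$atoms$is_frozen[hit] <- TRUE
    }
  }
  rownames(sub$atoms) <- NULL
  validate_structure(sub)

  model <- structure(list(structure = sub, recipe = recipe, variant = variant,
                          report = list(
                            n_atoms = n_atoms(sub),
                            n_caps = sum(sub$atoms$is_cap),
                            frozen_serials = sub$atoms$serial[sub$atoms$is_frozen],
                            warnings = character(0))),
                     class = "ClusterModel")
  validate_cluster_model(model)
  model
}

connected_component <- function(start, bonds, n) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds[i, 1]; b <- bonds[i, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n); stack <- start; seen[start] <- TRUE
  while (length(stack) > 0) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
  }
  which(seen)
}

validate_cluster_model <- function(model) {
  a <- model$structure$atoms
  if (any(a$is_cap & !a$is_frozen)) stop("cluster invariant violated: unfrozen cap atom")
  n_cuts <- length(model$recipe$truncations)
  if (sum(a$is_cap) != n_cuts) {
    stop(sprintf("cluster invariant violated: %d caps for %d truncations",
                 sum(a$is_cap), n_cuts))
  }
  invisible(model)
}

#' @export
print.ClusterModel <- function(x, ...) {
  cat(sprintf("ClusterModel '%s': %d atoms (%d caps, %d frozen), charge %+d\n",
              x$variant, n_atoms(x$structure), sum(x$structure$atoms$is_cap),
              sum(x$structure$atoms$is_frozen), x$recipe$charge))
  invisible(x)
}

# ---- hydrogen addition -----------------------------------------------------

# Deterministic hydrogen placement on one heavy atom given its bonded
# neighbours. Returns a list of position vectors.
place_h_positions <- function(pos, nb_pos, n_add, sp2, bond_len, ref_pos = NULL) {
  if (n_add <= 0) return(list())
  k <- length(nb_pos)
  theta <- if (sp2) 120 else 109.47
  if (k == 0) {
    # free molecule (water): fixed template orientation
    out <- list(pos + c(bond_len, 0, 0))
    if (n_add >= 2) {
      ang <- 104.5 * pi / 180
      out <- c(out, list(pos + bond_len * c(cos(ang), sin(ang), 0)))
    }
    return(out[seq_len(n_add)])
  }
  if (k == 1) {
    nb <- nb_pos[[1]]
    a <- ref_pos %||% {
      # deterministic off-axis reference point
      w <- unit(pos - nb)
      p <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      nb + unit(pracma_cross(w, p))
    }
    tor0 <- if (sp2) 0 else 180
    return(lapply(seq_len(n_add), function(i) {
      nerf_place(a, nb, pos, bond_len, theta, tor0 + (i - 1) * 120)
    }))
  }
  if (k == 2) {
    u1 <- unit(nb_pos[[1]] - pos); u2 <- unit(nb_pos[[2]] - pos)
    if (n_add == 1) return(list(pos + bond_len * unit(-(u1 + u2))))
    b <- unit(-(u1 + u2)); p <- unit(pracma_cross(u1, u2))
    half <- 109.47 / 2 * pi / 180
    out <- list(pos + bond_len * (cos(half) * b + sin(half) * p),
                pos + bond_len * (cos(half) * b - sin(half) * p))
    if (n_add > 2) {
      warning("cannot place more than 2 hydrogens on a 2-neighbour centre",
              call. = FALSE)
    }
    return(out[seq_len(min(n_add, 2))])
  }
  dirs <- lapply(nb_pos, function(q) unit(q - pos))
  v <- -Reduce(`+`, dirs)
  if (vnorm(v) < 1e-6) v <- pracma_cross(dirs[[1]], dirs[[2]])
  if (n_add > 1) {
    warning("cannot place more than 1 hydrogen on a >=3-neighbour centre",
            call. = FALSE)
  }
  list(pos + bond_len * unit(v))
}

#' Add hydrogens from geometric templates
#'
#' Places missing hydrogens on every heavy atom using per-residue expected
#' counts and idealized local geometry (tetrahedral or trigonal frames;
#' water gets two H at 0.96 Angstrom and 104.5 degrees). Protonation states
#' are explicit user input: every titratable residue present
#' (Asp/Glu/His/Tyr/Cys/Arg/Lys) must appear in `protonation`, keyed by
#' residue key — there is no silent default. Already-present hydrogens are
#' kept, so the operation is idempotent.
#'
#' Added hydrogens are never frozen unless they sit on a frozen cap
#' attachment atom.
#'
#' @param model a `ClusterModel` or plain `Structure`.
#' @param protonation named list/character vector: residue key -> state tag
#'   (`"anionic"`/`"neutral"` for Asp/Glu, `"thiol"`/`"thiolate"` for Cys,
#'   `"neutral"`/`"anionic"` for Tyr, `"protonated"`/`"neutral"` for Lys,
#'   `"protonated"` for Arg, `"HID"`/`"HIE"`/`"HIP"` for His).
#' @return object of the same class with hydrogens added.
#' @export
add_hydrogens <- function(model, protonation = list()) {
  is_model <- inherits(model, "ClusterModel")
  s <- if (is_model) model$structure else model
  akeys <- atom_res_keys(s)

  titr <- unique(akeys[toupper(s$atoms$resname) %in% .TITRATABLE])
  undeclared <- setdiff(titr, names(protonation))
  if (length(undeclared) > 0) {
    stop("protonation state not declared for titratable residue(s): ",
         paste(undeclared, collapse = ", "))
  }

  bonds <- detect_bonds(s)
  adj <- vector("list", nrow(s$atoms))
  for (i in seq_len(nrow(bonds))) {
    a <- bonds[i, 1]; b <- bonds[i, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  xyz <- atom_xyz(s)
  is_h <- toupper(s$atoms$element) == "H"
  new_rows <- list()
  next_serial <- max(s$atoms$serial) + 1L

  for (i in seq_len(nrow(s$atoms))) {
    if (is_h[i] || s$atoms$is_cap[i]) next
    resname <- toupper(s$atoms$resname[i])
    state <- protonation[[akeys[i]]]
    nH <- h_count(resname, s$atoms$name[i], state)
    nbrs <- adj[[i]] %||% integer(0)
    # cap hydrogens stand in for the severed heavy neighbour, not for a
    # template hydrogen slot
    have_h <- sum(is_h[nbrs] & !s$atoms$is_cap[nbrs])
    need <- nH - have_h
    if (need <= 0) next
    heavy_nb <- nbrs[!is_h[nbrs]]
    nb_pos <- lapply(heavy_nb, function(j) xyz[j, ])
    ref <- NULL
    if (length(heavy_nb) == 1) {
      gp <- setdiff(adj[[heavy_nb[1]]], i)
      gp <- gp[!is_h[gp]]
      if (length(gp) > 0) ref <- xyz[gp[1], ]
    }
    # existing H on this atom also constrain placement
    h_nb <- nbrs[is_h[nbrs]]
    nb_all <- c(nb_pos, lapply(h_nb, function(j) xyz[j, ]))
    bl <- .H_BOND_LENGTH[[toupper(s$atoms$element[i])]] %||% 1.0
    pos_list <- place_h_positions(xyz[i, ], nb_all, need,
                                  is_sp2_atom(resname, s$atoms$name[i]), bl, ref)
    base <- sub("^[A-Za-z]", "", s$atoms$name[i])
    for (j in seq_along(pos_list)) {
      row <- s$atoms[i, , drop = FALSE]
      row$serial <- next_serial; next_serial <- next_serial + 1L
      nm <- if (length(pos_list) == 1 && have_h == 0) paste0("H", base)
            else paste0("H", base, have_h + j)
      # keep names unique within this residue only
      same_res <- vapply(new_rows, function(r) {
        res_key(r$chain, r$resnum, r$icode) == akeys[i]
      }, logical(1))
      taken <- c(s$atoms$name[akeys == akeys[i]],
                 vapply(new_rows[same_res], function(r) r$name, character(1)))
      while (nm %in% taken) nm <- paste0(nm, "X")
      row$name <- nm
      row$element <- "H"
      row$x <- pos_list[[j]][1]; row$y <- pos_list[[j]][2]; row$z <- pos_list[[j]][3]
      row$is_cap <- FALSE
      row$is_frozen <- s$atoms$is_frozen[i] && any(s$atoms$is_cap[nbrs])
      new_rows[[length(new_rows) + 1]] <- row
    }
  }
  if (length(new_rows) > 0) {
    all <- rbind(s$atoms, do.call(rbind, new_rows))
    # keep each residue's atoms contiguous (stable within-residue order)
    fac <- factor(res_key(all$chain, all$resnum, all$icode),
                  levels = unique(akeys))
    all <- all[order(as.integer(fac)), , drop = FALSE]
    rownames(all) <- NULL
    s$atoms <- all
  }
  validate_structure(s)
  if (is_model) { model$structure <- s; model } else s
}

# ---- mutation --------------------------------------------------------------

#' Apply one point mutation to a cluster model
#'
#' Replaces a residue's side chain with an idealized template of the target
#' residue. Backbone and attachment atoms (N, CA, C, O, CB and their
#' hydrogens) are preserved bitwise; the new side chain is grown beyond CB by
#' internal-coordinate construction, inheriting the parent's chi1 torsion
#' where the target has a corresponding bond, so the crystal-frame pocket
#' shape is kept. Frozen flags survive on retained atoms; new atoms start
#' unfrozen. Atoms of other residues are untouched.
#'
#' If the parent side chain carried hydrogens, the new side chain is
#' re-hydrogenated from the same templates (a `protonation` state is then
#' required for titratable targets such as Cys).
#'
#' A new atom closer than 1 Angstrom to any retained atom triggers a clash
#' warning (recorded in the model report, not an error: downstream geometry
#' optimization relieves clashes).
#'
#' @param model a `ClusterModel`.
#' @param key residue key of the mutated residue.
#' @param from,to 3-letter codes; `from` must match the residue present.
#' @param chi1 optional chi1 override in degrees (default: inherit).
#' @param protonation state tag for the new residue if titratable.
#' @return the mutated `ClusterModel`.
#' @export
mutate_residue <- function(model, key, from, to, chi1 = NULL, protonation = NULL) {
  stopifnot(inherits(model, "ClusterModel"))
  from <- toupper(from); to <- toupper(to)
  s <- model$structure
  akeys <- atom_res_keys(s)
  idx <- which(akeys == key)
  if (length(idx) == 0) stop("residue not found: ", key)
  res <- s$atoms[idx, , drop = FALSE]
  present <- toupper(res$resname[1])
  if (present != from) {
    stop(sprintf("from-code mismatch at %s: model has %s, mutation says %s",
                 key, present, from))
  }
  if (!(to %in% names(.SIDECHAIN_TEMPLATES))) {
    stop("no side-chain template for residue type: ", to)
  }
  if (from == to) return(model)

  backbone <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3", "HA",
                "HA1", "HA2", "HA3", "HXT")
  keep_names <- backbone
  if (to != "GLY") keep_names <- c(keep_names, "CB")
  keep_names <- c(keep_names, res$name[res$is_cap])  # caps stay put
  keep <- res$name %in% keep_names
  had_sidechain_h <- any(toupper(res$element) == "H" &
                           !(res$name %in% backbone) & !res$is_cap)

  coords <- list()
  for (i in which(keep)) coords[[res$name[i]]] <- c(res$x[i], res$y[i], res$z[i])
  for (nm in c("N", "CA")) {
    if (is.null(coords[[nm]])) stop("cannot mutate ", key, ": backbone atom ", nm, " missing")
  }
  if (to != "GLY" && is.null(coords[["CB"]])) {
    stop("cannot mutate ", key, ": attachment atom CB missing")
  }

  # inherit chi1 from the parent where defined
  if (is.null(chi1)) {
    gp <- .GAMMA_ATOM[[present]]
    chi1 <- 180
    if (!is.null(gp) && gp %in% res$name && all(c("N", "CA", "CB") %in% res$name)) {
      g <- function(nm) { r <- res[res$name == nm, ]; c(r$x, r$y, r$z) }
      chi1 <- torsion_deg(g("N"), g("CA"), g("CB"), g(gp))
    }
  }

  tmpl <- .SIDECHAIN_TEMPLATES[[to]]
  new_atoms <- list()
  for (ta in tmpl) {
    refs <- lapply(ta$refs, function(nm) coords[[nm]])
    if (any(vapply(refs, is.null, logical(1)))) {
      stop("template reference atom missing while mutating ", key, " to ", to)
    }
    dih <- if (is.list(ta$dihedral)) chi1 + ta$dihedral$chi else ta$dihedral
    p <- nerf_place(refs[[1]], refs[[2]], refs[[3]], ta$bond, ta$angle, dih)
    coords[[ta$name]] <- p
    new_atoms[[length(new_atoms) + 1]] <- list(name = ta$name, element = ta$element, pos = p)
  }

  kept_rows <- res[keep, , drop = FALSE]
  kept_rows$resname <- to
  new_rows <- NULL
  if (length(new_atoms) > 0) {
    new_rows <- do.call(rbind, lapply(new_atoms, function(na) {
      row <- kept_rows[1, , drop = FALSE]
      row$name <- na$name; row$element <- na$element
      row$x <- na$pos[1]; row$y <- na$pos[2]; row$z <- na$pos[3]
      row$is_frozen <- FALSE; row$is_cap <- FALSE
      row$serial <- NA_integer_
      row
    }))
  }

  other <- s$atoms[-idx, , drop = FALSE]
  res_new <- rbind(kept_rows, new_rows)
  if (any(is.na(res_new$serial))) {
    res_new$serial[is.na(res_new$serial)] <-
      max(s$atoms$serial) + seq_len(sum(is.na(res_new$serial)))
  }

  # clash scan against everything retained outside the mutated residue
  warnings <- model$report$warnings
  if (!is.null(new_rows) && nrow(other) > 0) {
    for (i in seq_len(nrow(new_rows))) {
      d <- sqrt((other$x - new_rows$x[i])^2 + (other$y - new_rows$y[i])^2 +
                  (other$z - new_rows$z[i])^2)
      if (any(d < 1.0)) {
        j <- which.min(d)
        w <- sprintf("steric clash: %s %s at %.2f A from %s %s:%d",
                     to, new_rows$name[i], min(d), other$name[j],
                     other$chain[j], other$resnum[j])
        warning(w, call. = FALSE)
        warnings <- c(warnings, w)
      }
    }
  }

  # reassemble preserving residue order
  pieces <- split(seq_len(nrow(s$atoms)), factor(akeys, levels = unique(akeys)))
  out <- do.call(rbind, lapply(names(pieces), function(k) {
    if (k == key) res_new else s$atoms[pieces[[k]], , drop = FALSE]
  }))
  rownames(out) <- NULL
  s$atoms <- out
  model$structure <- s
  model$report$warnings <- warnings
  model$report$n_atoms <- n_atoms(s)

  if (had_sidechain_h) {
    prot <- list()
    if (to %in% .TITRATABLE) {
      if (is.null(protonation)) {
        stop(sprintf("mutating %s to titratable %s requires a protonation state", key, to))
      }
      prot[[key]] <- protonation
    }
    model <- rehydrogenate_residue(model, key, prot)
  }
  validate_structure(model$structure)
  model
}

# add_hydrogens restricted to one residue (others assumed complete)
rehydrogenate_residue <- function(model, key, protonation) {
  s <- model$structure
  akeys <- atom_res_keys(s)
  # temporarily declare all other titratable residues as-is by passing their
  # current H through idempotence: give them a dummy state matching H present
  titr <- unique(akeys[toupper(s$atoms$resname) %in% .TITRATABLE & akeys != key])
  for (k in titr) {
    if (is.null(protonation[[k]])) protonation[[k]] <- infer_state(s, k)
  }
  out <- add_hydrogens(s, protonation)
  model$structure <- out
  model$report$n_atoms <- n_atoms(out)
  model
}

# Infer the protonation tag of an already-hydrogenated titratable residue
# from the hydrogens present (used only to keep them untouched).
infer_state <- function(s, key) {
  res <- s$atoms[atom_res_keys(s) == key, , drop = FALSE]
  resname <- toupper(res$resname[1])
  bonds <- detect_bonds(new_structure(res))
  h_on <- function(atom) {
    i <- which(res$name == atom)
    if (length(i) == 0) return(0L)
    nb <- c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
    sum(toupper(res$element[nb]) == "H")
  }
  switch(resname,
    ASP = if (h_on("OD2") > 0) "neutral" else "anionic",
    GLU = if (h_on("OE2") > 0) "neutral" else "anionic",
    CYS = if (h_on("SG") > 0) "thiol" else "thiolate",
    TYR = if (h_on("OH") > 0) "neutral" else "anionic",
    LYS = if (h_on("NZ") >= 3) "protonated" else "neutral",
    ARG = "protonated",
    HIS = {
      nd <- h_on("ND1") > 0; ne <- h_on("NE2") > 0
      if (nd && ne) "HIP" else if (nd) "HID" else "HIE"
    },
    "anionic")
}

#' Variant specification
#'
#' A named set of point mutations, e.g. the iterative saturation mutagenesis
#' variants of an engineering campaign (`R1 = Leu74Ile + Ile80Cys`).
#'
#' @param name variant label.
#' @param mutations list of `list(key =, from =, to =, protonation = NULL)`.
#' @export
variant_spec <- function(name, mutations = list()) {
  for (m in mutations) {
    if (!all(c("key", "from", "to") %in% names(m))) {
      stop("each mutation needs key, from and to")
    }
  }
  structure(list(name = name, mutations = mutations), class = "variant_spec")
}

#' Apply a variant (sequence of point mutations) to a cluster model
#'
#' Runs [mutate_residue()] for each mutation in order and records the variant
#' label. Mutations at non-adjacent sites commute, so the order is a
#' convention, not a result.
#'
#' @param model a `ClusterModel` (typically the wild-type model).
#' @param variant a [variant_spec()].
#' @export
apply_variant <- function(model, variant) {
  stopifnot(inherits(variant, "variant_spec"))
  for (m in variant$mutations) {
    model <- mutate_residue(model, m$key, m$from, m$to,
                            protonation = m$protonation %||% NULL)
  }
  model$variant <- variant$name
  model
}
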