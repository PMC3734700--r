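#' Atomic structure container
#'
#' A `Structure` stores an ordered atom table together with a title. It is
#' the common currency of the package: the PDB/XYZ readers produce one, the
#' cluster builder consumes and produces them, and the geometry diagnostics
#' operate on them.
#'
#' The atom table has one row per atom with columns:
#' \describe{
#'   \item{serial}{integer atom id, unique within the structure}
#'   \item{name}{atom name (e.g. `"CA"`, `"OD1"`)}
#'   \item{element}{element symbol}
#'   \item{resname}{3-letter residue code}
#'   \item{chain, resnum, icode}{residue key components}
#'   \item{x, y, z}{coordinates in Angstrom}
#'   \item{is_het}{TRUE for ligand/hetero atoms}
#'   \item{is_frozen}{TRUE for atoms locked during geometry optimization}
#'   \item{is_cap}{TRUE for link hydrogens added at truncation points}
#' }
#'
#' @param atoms data.frame with the columns listed above (missing flag
#'   columns are filled with defaults).
#' @param title character scalar.
#' @return An object of class `Structure`.
#' @export
new_structure <- function(atoms, title = "") {
  needed <- c("serial", "name", "element", "resname", "chain", "resnum",
              "icode", "x", "y", "z")
  for (col in c("is_het", "is_frozen", "is_cap")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- FALSE
  }
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  atoms <- atoms[, c(needed, "is_het", "is_frozen", "is_cap")]
  atoms$serial <- as.integer(atoms$serial)
  atoms$resnum <- as.integer(atoms$resnum)
  rownames(atoms) <- NULL
  s <- structure(list(atoms = atoms, title = as.character(title)[1]),
                 class = "Structure")
  validate_structure(s)
  s
}

validate_structure <- function(s) {
  a <- s$atoms
  if (anyDuplicated(a$serial)) stop("atom serials are not unique")
  bad <- !(toupper(a$element) %in% .ELEMENTS)
  if (any(bad)) {
    stop("invalid element symbol(s): ",
         paste(unique(a$element[bad]), collapse = ", "))
  }
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z))) {
    stop("non-finite atomic coordinates")
  }
  if (any(a$is_cap & toupper(a$element) != "H")) {
    stop("cap atoms must be hydrogen")
  }
  invisible(s)
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues%s\n", n_atoms(x),
              length(residue_keys(x)),
              if (nzchar(x$title)) paste0(" (", x$title, ")") else ""))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `Structure`.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Residue key string
#'
#' Residues are keyed as `"<chain>:<resnum>"` with any insertion code
#' appended (`"A:101"`, `"A:101A"`).
#' @param chain,resnum,icode key components (vectorized).
#' @export
res_key <- function(chain, resnum, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste0(chain, ":", resnum, icode)
}

atom_res_keys <- function(s) res_key(s$atoms$chain, s$atoms$resnum, s$atoms$icode)

#' Unique residue keys, in order of first appearance
#' @param s a `Structure`.
#' @export
residue_keys <- function(s) unique(atom_res_keys(s))

#' Extract one residue's atom rows
#' @param s a `Structure`.
#' @param key residue key (see [res_key()]).
#' @export
get_residue <- function(s, key) {
  rows <- s$atoms[atom_res_keys(s) == key, , drop = FALSE]
  if (nrow(rows) == 0) stop("residue not found: ", key)
  rows
}

atom_xyz <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

# Infer element from a PDB atom name when columns 77-78 are blank.
infer_element <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  if (nchar(nm) >= 2 && toupper(substr(nm, 1, 2)) %in% .ELEMENTS &&
      !(toupper(substr(nm, 1, 2)) %in% c("CA", "CD", "CE", "CG", "HB",
                                         "HD", "HE", "HG", "HH", "ND",
                                         "NE", "NH", "OD", "OE", "OG",
                                         "OH", "SD", "SG", "CB", "CZ",
                                         "NZ", "CH", "HZ", "HA"))) {
    return(toupper(substr(nm, 1, 2)))
  }
  toupper(substr(nm, 1, 1))
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records (fixed-column format). HETATM records become
#' ligand residues (`is_het = TRUE`). Alternate locations are resolved to the
#' highest-occupancy conformer (ties go to the first listed). Frozen and cap
#' flags written by [write_pdb()] are recovered from `REMARK 250 QMCLUST`
#' records, so the flags round-trip.
#'
#' The parse is never silently lossy: `attr(s, "n_records")` counts the
#' ATOM/HETATM records seen and `attr(s, "n_skipped")` the alternate-location
#' duplicates dropped, so `n_records == n_atoms + n_skipped` always holds.
#'
#' @param path path to a PDB file.
#' @return a [new_structure()] `Structure`, coordinates in Angstrom.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  atom_lines <- lines[is_atom]
  atom_lineno <- which(is_atom)
  if (length(atom_lines) == 0) stop("empty structure: no ATOM/HETATM records in ", path)

  num <- function(txt, lineno, what) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("unparsable %s in PDB record at line %d: '%s'",
                   what, lineno[bad[1]], trimws(txt[bad[1]])))
    }
    v
  }
  f <- function(a, b) substr(atom_lines, a, b)
  occ_txt <- trimws(f(55, 60))
  occ <- suppressWarnings(as.numeric(occ_txt))
  occ[is.na(occ)] <- 1.0
  elem_txt <- trimws(f(77, 78))
  name <- trimws(f(13, 16))
  elem <- ifelse(nzchar(elem_txt), toupper(elem_txt),
                 vapply(name, infer_element, character(1)))
  atoms <- data.frame(
    serial = as.integer(num(f(7, 11), atom_lineno, "serial")),
    name = name,
    element = elem,
    altloc = f(17, 17),
    resname = trimws(f(18, 20)),
    chain = f(22, 22),
    resnum = as.integer(num(f(23, 26), atom_lineno, "residue number")),
    icode = f(27, 27),
    x = num(f(31, 38), atom_lineno, "x coordinate"),
    y = num(f(39, 46), atom_lineno, "y coordinate"),
    z = num(f(47, 54), atom_lineno, "z coordinate"),
    occ = occ,
    is_het = substr(atom_lines, 1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
  n_records <- nrow(atoms)

  # Resolve altlocs: keep the highest-occupancy conformer per
  # (residue, atom name); ties -> first listed.
  keep <- rep(TRUE, n_records)
  has_alt <- atoms$altloc != " " & atoms$altloc != ""
  if (any(has_alt)) {
    grp <- paste(atoms$chain, atoms$resnum, atoms$icode, atoms$name)
    for (g in unique(grp[has_alt])) {
      idx <- which(grp == g)
      if (length(idx) > 1) {
        best <- idx[which.max(atoms$occ[idx])]  # which.max: first of ties
        keep[setdiff(idx, best)] <- FALSE
      }
    }
  }
  n_skipped <- sum(!keep)
  atoms <- atoms[keep, , drop = FALSE]
  atoms$icode <- ifelse(atoms$icode == " ", "", atoms$icode)
  atoms$altloc <- NULL
  atoms$occ <- NULL

  # Recover frozen/cap flags from REMARK 250 QMCLUST records.
  flag_serials <- function(tag) {
    rl <- lines[grepl(paste0("^REMARK 250 QMCLUST ", tag, " "), lines)]
    if (length(rl) == 0) return(integer(0))
    as.integer(unlist(strsplit(trimws(sub(
      paste0("^REMARK 250 QMCLUST ", tag, " "), "", rl)), "\\s+")))
  }
  atoms$is_frozen <- atoms$serial %in% flag_serials("FROZEN")
  atoms$is_cap <- atoms$serial %in% flag_serials("CAP")

  title_l <- lines[grepl("^TITLE ", lines)]
  title <- if (length(title_l) > 0) trimws(substr(title_l[1], 11, 80)) else ""
  s <- new_structure(atoms, title = title)
  attr(s, "n_records") <- n_records
  attr(s, "n_skipped") <- n_skipped
  s
}

#' Write a structure as PDB
#'
#' Writes standard ATOM/HETATM records with 3-decimal coordinates. Frozen and
#' cap flags are persisted in `REMARK 250 QMCLUST FROZEN/CAP` records listing
#' atom serials, so [read_pdb()] round-trips them.
#'
#' @param s a `Structure` (non-empty, at most 99999 atoms).
#' @param path output path.
#' @export
write_pdb <- function(s, path) {
  validate_structure(s)
  a <- s$atoms
  if (nrow(a) == 0) stop("refusing to write an empty structure")
  if (nrow(a) > 99999) stop("PDB format limit exceeded: more than 99999 atoms")
  out <- character(0)
  if (nzchar(s$title)) out <- c(out, sprintf("TITLE     %s", s$title))
  chunk <- function(ids, tag) {
    sp <- split(ids, ceiling(seq_along(ids) / 12))
    vapply(sp, function(g) paste("REMARK 250 QMCLUST", tag,
                                 paste(g, collapse = " ")), character(1))
  }
  if (any(a$is_frozen)) out <- c(out, chunk(a$serial[a$is_frozen], "FROZEN"))
  if (any(a$is_cap)) out <- c(out, chunk(a$serial[a$is_cap], "CAP"))
  pdb_name <- function(nm, el) {
    # column-13 alignment rule: 1-letter elements start in column 14
    if (nchar(nm) >= 4) return(substr(nm, 1, 4))
    if (nchar(el) == 1) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
  }
  recs <- vapply(seq_len(nrow(a)), function(i) {
    sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            if (a$is_het[i]) "HETATM" else "ATOM",
            a$serial[i], pdb_name(a$name[i], a$element[i]), " ",
            a$resname[i], a$chain[i], a$resnum[i],
            if (nzchar(a$icode[i])) a$icode[i] else " ",
            a$x[i], a$y[i], a$z[i], 1.0, 0.0, a$element[i])
  }, character(1))
  out <- c(out, recs, "END")
  writeLines(out, path)
  invisible(path)
}

#' Write a structure in XYZ format
#'
#' First line atom count, second line title, then one `element x y z` line
#' per atom with 6-decimal coordinates (the format QM engines consume).
#'
#' @param s a `Structure`.
#' @param path output path.
#' @export
write_xyz <- function(s, path) {
  a <- s$atoms
  lines <- c(sprintf("%d", nrow(a)), s$title,
             sprintf("%-2s %14.6f %14.6f %14.6f", a$element, a$x, a$y, a$z))
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZ file
#'
#' Inverse of [write_xyz()]; all atoms are assigned to a single placeholder
#' residue `UNK 1` since XYZ carries no topology.
#'
#' @param path path to an XYZ file.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n)) stop("malformed XYZ: first line is not an atom count")
  title <- if (length(lines) >= 2) lines[2] else ""
  body <- lines[3:(2 + n)]
  parts <- strsplit(trimws(body), "\\s+")
  atoms <- data.frame(
    serial = seq_len(n),
    name = vapply(parts, `[[`, character(1), 1),
    element = toupper(vapply(parts, `[[`, character(1), 1)),
    resname = "UNK", chain = "X", resnum = 1L, icode = "",
    x = as.numeric(vapply(parts, `[[`, character(1), 2)),
    y = as.numeric(vapply(parts, `[[`, character(1), 3)),
    z = as.numeric(vapply(parts, `[[`, character(1), 4)),
    stringsAsFactors = FALSE
  )
  new_structure(atoms, title = title)
}

# Bond perception by covalent radii: pairs closer than scale * (r_i + r_j).
# Returns a 2-column matrix of atom-row indices.
detect_bonds <- function(s, scale = 1.25) {
  xyz <- atom_xyz(s)
  el <- toupper(s$atoms$element)
  r <- .COV_RADII[el]
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(r, r, "+") * scale
  hit <- which(d < thr & upper.tri(d), arr.ind = TRUE)
  hit <- hit[d[hit] > 0.4, , drop = FALSE]  # guard against duplicates
  unname(hit)
}
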