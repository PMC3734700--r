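#' Valence angle between three points
#'
#' Angle a-b-c in degrees, in [0, 180] — e.g. the nucleophilic O-C-O attack
#' angle monitored on epoxide-opening transition states as a steric-strain
#' indicator. Invariant under rigid motion of all three points.
#'
#' @param a,b,c positions (length-3 numeric vectors); `b` is the vertex.
#' @export
vec_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-12 || nv < 1e-12) stop("zero-length arm: vertex coincides with an endpoint")
  cth <- sum(u * v) / (nu * nv)
  cth <- min(1, max(-1, cth))
  acos(cth) * 180 / pi
}

#' Angle probe on a structure
#'
#' Resolves three atom selectors (`"chain:resnum:atom"`) and measures the
#' angle at the middle atom.
#'
#' @param s a `Structure`.
#' @param sel_a,sel_b,sel_c atom selectors; `sel_b` is the vertex (e.g. the
#'   attacked carbon in an O-C-O probe).
#' @export
angle_probe <- function(s, sel_a, sel_b, sel_c) {
  pos <- function(sel) {
    p <- parse_selector(sel)
    rows <- s$atoms[atom_res_keys(s) == p$key & s$atoms$name == p$name, , drop = FALSE]
    if (nrow(rows) != 1) stop("selector must match exactly one atom: ", sel,
                              " (matched ", nrow(rows), ")")
    c(rows$x, rows$y, rows$z)
  }
  vec_angle(pos(sel_a), pos(sel_b), pos(sel_c))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1) and translation minimizing the RMSD
#' of paired atoms, via SVD of the covariance matrix. At least three
#' non-collinear pairs are required.
#'
#' @param mobile,reference `Structure`s or n-by-3 coordinate matrices.
#' @param pairs optional 2-column matrix of atom serials (mobile, reference);
#'   default pairs atoms by order (requires equal atom counts).
#' @return list with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom); applying `x %*% t(rotation) + translation` to the mobile
#'   subset superposes it on the reference.
#' @export
superpose <- function(mobile, reference, pairs = NULL) {
  as_xyz <- function(s, serials = NULL) {
    if (inherits(s, "Structure")) {
      if (is.null(serials)) return(atom_xyz(s))
      idx <- match(serials, s$atoms$serial)
      if (any(is.na(idx))) stop("pair serial(s) not found in structure")
      atom_xyz(s)[idx, , drop = FALSE]
    } else as.matrix(s)
  }
  X <- as_xyz(mobile, if (!is.null(pairs)) pairs[, 1])
  Y <- as_xyz(reference, if (!is.null(pairs)) pairs[, 2])
  if (nrow(X) != nrow(Y)) stop("superposition subsets differ in size")
  if (nrow(X) < 3) stop("need at least 3 atom pairs for a rigid superposition")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  # collinearity check: rank of the centered cloud
  if (svd(Xc)$d[2] < 1e-8 * max(1, svd(Xc)$d[1])) {
    stop("superposition subset is collinear")
  }
  H <- t(Xc) %*% Yc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cy - as.numeric(R %*% cx)
  moved <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Yc)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

#' Overlay consistency of two stationary-point structures
#'
#' Checks that groups not directly participating in the reaction sit in the
#' same local minimum in both structures: superposes the two on their frozen
#' (locked) atoms — the crystallographic frame of the cluster — and reports
#' the per-residue heavy-atom RMSD, flagging residues above the threshold.
#' Reacting residues are excluded from the comparison.
#'
#' @param point_a,point_b `Structure`s with identical atom sets after
#'   exclusion (matched by residue key + atom name).
#' @param exclude residue keys of the reacting groups to ignore.
#' @param threshold per-residue heavy-atom RMSD flag threshold, Angstrom.
#' @return data.frame (`residue`, `rmsd`, `flagged`) with attributes
#'   `frozen_rmsd` and `threshold`.
#' @export
conformer_consistency <- function(point_a, point_b, exclude = character(0),
                                  threshold = 0.3) {
  tag <- function(s) paste(atom_res_keys(s), s$atoms$name)
  keep_a <- !(atom_res_keys(point_a) %in% exclude)
  keep_b <- !(atom_res_keys(point_b) %in% exclude)
  a <- point_a$atoms[keep_a, , drop = FALSE]
  b <- point_b$atoms[keep_b, , drop = FALSE]
  ta <- paste(res_key(a$chain, a$resnum, a$icode), a$name)
  tb <- paste(res_key(b$chain, b$resnum, b$icode), b$name)
  if (!setequal(ta, tb) || anyDuplicated(ta) || anyDuplicated(tb)) {
    diff <- union(setdiff(ta, tb), setdiff(tb, ta))
    stop("atom sets differ after exclusion: ", paste(diff, collapse = ", "))
  }
  b <- b[match(ta, tb), , drop = FALSE]

  frozen <- a$is_frozen & b$is_frozen
  if (sum(frozen) < 3) stop("need at least 3 shared frozen atoms to define the overlay frame")
  Xa <- as.matrix(a[, c("x", "y", "z")])
  Xb <- as.matrix(b[, c("x", "y", "z")])
  fit <- superpose(Xa[frozen, , drop = FALSE], Xb[frozen, , drop = FALSE])
  Xa_fit <- sweep(Xa %*% t(fit$rotation), 2, fit$translation, `+`)

  heavy <- toupper(a$element) != "H"
  keys <- res_key(a$chain, a$resnum, a$icode)
  res_list <- unique(keys)
  rmsd <- vapply(res_list, function(k) {
    sel <- keys == k & heavy
    if (!any(sel)) return(0)
    sqrt(mean(rowSums((Xa_fit[sel, , drop = FALSE] - Xb[sel, , drop = FALSE])^2)))
  }, numeric(1))
  out <- data.frame(residue = res_list, rmsd = unname(rmsd),
                    flagged = unname(rmsd) > threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "frozen_rmsd") <- fit$rmsd
  attr(out, "threshold") <- threshold
  out
}
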