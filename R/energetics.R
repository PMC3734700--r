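#' Stationary point with two-level energy components
#'
#' Pairs the optimization-level result (source of the zero-point correction)
#' with the large-basis single-point result (source of electronic, solvation
#' and dispersion components), mirroring the usual two-level cluster
#' protocol: geometries and frequencies from a small basis, energies from a
#' larger one. When only one combined record exists, pass it as both.
#'
#' Transition-state labels (anything starting `TS`) are validated: a result
#' with a known imaginary-mode count must have exactly one to be accepted; an
#' unknown count is accepted with a warning.
#'
#' @param label one of `"ES"`, `"TS_C1"`, `"TS_C2"`, `"product"` (or any
#'   `TS*` label for additional conformers).
#' @param opt optimization-level [qm_result()].
#' @param sp single-point-level [qm_result()] (defaults to `opt`).
#' @export
stationary_point <- function(label, opt, sp = opt) {
  stopifnot(inherits(opt, "QMResult"), inherits(sp, "QMResult"))
  if (grepl("^TS", label)) {
    if (!is.na(opt$n_imag) && opt$n_imag != 1L) {
      stop(sprintf("%s rejected: %d imaginary modes (a transition state needs exactly 1)",
                   label, opt$n_imag))
    }
    if (is.na(opt$n_imag)) {
      warning(label, " accepted without frequency validation (imaginary-mode count unknown)",
              call. = FALSE)
    }
  }
  structure(list(label = label, opt = opt, sp = sp), class = "StationaryPoint")
}

#' Corrected total energy of a stationary point
#'
#' The corrected energy is the large-basis electronic energy plus zero-point,
#' solvation and dispersion corrections:
#' `E = E_el(sp) + ZPE(opt) + dE_solv(sp) + dE_disp(sp)`, all kcal/mol.
#'
#' @param point a [stationary_point()].
#' @export
total_energy <- function(point) {
  stopifnot(inherits(point, "StationaryPoint"))
  for (r in list(point$opt, point$sp)) {
    if (!r$converged) {
      stop("unconverged component for job ", r$job_id, " at point ", point$label)
    }
  }
  point$sp$electronic_energy + point$opt$zpe + point$sp$solvation +
    point$sp$dispersion
}

#' Reaction profile of one enzyme variant
#'
#' Holds the stationary points of the competing enantiomer-forming pathways:
#' exactly one enzyme-substrate (ES) complex as energetic reference and at
#' least one transition state per pathway.
#'
#' @param variant variant label (`"WT"`, `"R1"`, ...).
#' @param points list of [stationary_point()] objects.
#' @param temperature note recorded with the profile, K.
#' @export
reaction_profile <- function(variant, points, temperature = 298.15) {
  labels <- vapply(points, function(p) p$label, character(1))
  if (sum(labels == "ES") != 1) stop("profile needs exactly one ES point")
  if (!any(grepl("^TS", labels))) stop("profile has no transition state")
  names(points) <- labels
  structure(list(variant = variant, points = points, temperature = temperature),
            class = "ReactionProfile")
}

#' Activation barrier for one pathway
#'
#' `total_energy(TS) - total_energy(ES)`, kcal/mol. Invariant to any uniform
#' shift of all energies.
#'
#' @param profile a [reaction_profile()].
#' @param ts_label transition-state label, e.g. `"TS_C1"`.
#' @export
barrier <- function(profile, ts_label) {
  stopifnot(inherits(profile, "ReactionProfile"))
  ts <- profile$points[[ts_label]]
  if (is.null(ts)) stop("no stationary point labelled ", ts_label,
                        " in profile ", profile$variant)
  total_energy(ts) - total_energy(profile$points[["ES"]])
}

#' Barrier difference between the enantiomer-forming pathways
#'
#' `barrier(TS_C2) - barrier(TS_C1)`, kcal/mol. With attack at C1 leading to
#' the S,S product and at C2 to the R,R product, a negative value means the
#' R,R pathway is lower — R,R-favored; positive means S,S-favored.
#'
#' When several TS conformers exist per pathway (labels `TS_C1`, `TS_C1b`,
#' ...), the lowest-energy conformer defines each pathway barrier
#' (Curtin-Hammett; see [boltzmann_ee()] for the fully weighted form).
#'
#' @param profile a [reaction_profile()].
#' @export
delta_delta_barrier <- function(profile) {
  pathway_barrier <- function(face) {
    labs <- names(profile$points)[grepl(paste0("^TS_", face), names(profile$points))]
    if (length(labs) == 0) stop("no TS_", face, " in profile ", profile$variant)
    min(vapply(labs, function(l) barrier(profile, l), numeric(1)))
  }
  pathway_barrier("C2") - pathway_barrier("C1")
}

#' Barrier table across variants
#'
#' One row per profile with the two pathway barriers and their difference —
#' the layout of a calculated-selectivity table. `delta_delta` always equals
#' `barrier_C2 - barrier_C1` at full precision; round only for display.
#'
#' @param profiles list of [reaction_profile()] objects.
#' @return data.frame with columns `variant`, `barrier_C1`, `barrier_C2`,
#'   `delta_delta`.
#' @export
barrier_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    b1 <- barrier(p, "TS_C1"); b2 <- barrier(p, "TS_C2")
    data.frame(variant = p$variant, barrier_C1 = b1, barrier_C2 = b2,
               delta_delta = b2 - b1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
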