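#' Engine-agnostic QM job specification
#'
#' A declarative description of one electronic-structure job: the geometry,
#' the task (`minimize` for ES/product optimization, `saddle-search` for
#' transition states, `single-point` for the large-basis energy), a free-form
#' level tag, charge/multiplicity, the frozen-atom list implementing the
#' coordinate-locking scheme, and an optional continuum dielectric.
#'
#' Job ids are deterministic: `<variant>/<point>/<task>/<level>`, so the same
#' model and protocol always map to the same id — the key used by the lookup
#' engine and the results table.
#'
#' @param model a `ClusterModel`.
#' @param task one of `"minimize"`, `"saddle-search"`, `"single-point"`.
#' @param level free level-of-theory tag (e.g. `"opt-small-basis"`).
#' @param point stationary-point label (`"ES"`, `"TS_C1"`, `"TS_C2"`, ...).
#' @param dielectric continuum dielectric constant, or NULL for gas phase.
#' @return a `QMJobSpec` object.
#' @export
build_job <- function(model, task = c("minimize", "saddle-search", "single-point"),
                      level = "opt-small-basis", point = "ES", dielectric = NULL) {
  stopifnot(inherits(model, "ClusterModel"))
  task <- match.arg(task)
  if (n_atoms(model$structure) == 0) stop("model is empty")
  frozen <- model$structure$atoms$serial[model$structure$atoms$is_frozen]
  structure(list(
    job_id = paste(model$variant, point, task, level, sep = "/"),
    geometry = model$structure,
    task = task, level = level, point = point,
    charge = model$recipe$charge, multiplicity = model$recipe$multiplicity,
    frozen = frozen, dielectric = dielectric
  ), class = "QMJobSpec")
}

#' QM result record
#'
#' Energy components for one stationary point, all in kcal/mol. Engines that
#' work in hartree convert at ingestion (627.509474 kcal/mol per hartree).
#'
#' @param job_id job id the result answers.
#' @param electronic_energy electronic energy, kcal/mol.
#' @param zpe zero-point vibrational correction, kcal/mol.
#' @param solvation continuum-solvation correction, kcal/mol.
#' @param dispersion dispersion correction, kcal/mol.
#' @param converged logical.
#' @param geometry final `Structure`, or NULL.
#' @param n_imag number of imaginary modes, or NA if not computed.
#' @export
qm_result <- function(job_id, electronic_energy, zpe = 0, solvation = 0,
                      dispersion = 0, converged = TRUE, geometry = NULL,
                      n_imag = NA_integer_) {
  if (converged && !is.finite(electronic_energy)) {
    stop("a converged result must carry a finite electronic energy")
  }
  structure(list(job_id = job_id, electronic_energy = electronic_energy,
                 zpe = zpe, solvation = solvation, dispersion = dispersion,
                 converged = isTRUE(converged), geometry = geometry,
                 n_imag = n_imag), class = "QMResult")
}

HARTREE_TO_KCAL <- 627.509474

#' Run a QM job through an engine
#'
#' Generic dispatch on the engine object. The contract: the engine returns a
#' [qm_result()] whose `job_id` matches the spec; a non-converged calculation
#' is reported as `converged = FALSE`, never as an R error.
#'
#' @param spec a `QMJobSpec` from [build_job()].
#' @param engine an engine object ([lookup_engine()] or [toy_engine()]).
#' @export
run_engine <- function(spec, engine) {
  stopifnot(inherits(spec, "QMJobSpec"))
  UseMethod("run_engine", engine)
}

#' @export
run_engine.default <- function(spec, engine) stop("unknown engine type")

#' Table-lookup engine
#'
#' Replays precomputed energy components keyed by job id — the mechanism by
#' which externally computed QM results (from any electronic-structure
#' package) enter the pipeline, and the engine used for all end-to-end
#' tests. Pure: identical spec, identical result.
#'
#' @param results a list of `QMResult` (e.g. from [parse_results_table()])
#'   or a path to a results table.
#' @export
lookup_engine <- function(results) {
  if (is.character(results)) results <- parse_results_table(results)
  ids <- vapply(results, function(r) r$job_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate job ids in results: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(results) <- ids
  structure(list(results = results), class = c("lookup_engine", "qm_engine"))
}

#' @export
run_engine.lookup_engine <- function(spec, engine) {
  r <- engine$results[[spec$job_id]]
  if (is.null(r)) stop("no result in lookup table for job id: ", spec$job_id)
  r
}

#' Parse a QM results table
#'
#' Tab/whitespace-delimited text with header columns `job_id`,
#' `electronic_energy`, `zpe`, `solvation`, `dispersion`, `converged`,
#' `n_imag`; energies in kcal/mol; `#` comment lines ignored.
#'
#' @param path path to the table.
#' @return list of [qm_result()] records, one per row.
#' @export
parse_results_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "", comment.char = "#",
                          stringsAsFactors = FALSE)
  needed <- c("job_id", "electronic_energy", "zpe", "solvation",
              "dispersion", "converged", "n_imag")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("results table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$job_id)) {
    stop("duplicate job id(s) in results table: ",
         paste(unique(df$job_id[duplicated(df$job_id)]), collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    qm_result(df$job_id[i], df$electronic_energy[i], df$zpe[i],
              df$solvation[i], df$dispersion[i],
              converged = as.logical(df$converged[i]),
              n_imag = suppressWarnings(as.integer(df$n_imag[i])))
  })
}

# ---- toy engine ------------------------------------------------------------

#' Deterministic closed-form toy engine
#'
#' A desk-scale stand-in for an electronic-structure package. The energy is
#'
#'   E = sum_bonds k (r - r0)^2  +  sum_{i<j} A exp(-r_ij / rho)
#'
#' with `k = 300` kcal/mol/A^2, bond reference lengths `r0` from covalent
#' radii, and a soft exponential repulsion (`A = 500` kcal/mol,
#' `rho = 0.4` A) over all atom pairs. Bonds are perceived once on the input
#' geometry. Because the energy depends only on interatomic distances it is
#' invariant under rigid rotation and translation.
#'
#' `minimize` runs gradient descent on the unfrozen atoms; `single-point`
#' evaluates the closed form. Saddle searches are not supported.
#'
#' @param k,A,rho force-field parameters (see above).
#' @param max_steps,step,tol gradient-descent controls.
#' @export
toy_engine <- function(k = 300, A = 500, rho = 0.4,
                       max_steps = 500, step = 1e-3, tol = 1e-8) {
  structure(list(k = k, A = A, rho = rho, max_steps = max_steps,
                 step = step, tol = tol),
            class = c("toy_engine", "qm_engine"))
}

toy_energy_gradient <- function(xyz, elements, bonds, eng) {
  n <- nrow(xyz)
  grad <- matrix(0, n, 3)
  e <- 0
  r0 <- unname(.COV_RADII[toupper(elements)])
  if (nrow(bonds) > 0) {
    for (bi in seq_len(nrow(bonds))) {
      i <- bonds[bi, 1]; j <- bonds[bi, 2]
      d <- xyz[i, ] - xyz[j, ]
      r <- vnorm(d)
      ref <- r0[i] + r0[j]
      e <- e + eng$k * (r - ref)^2
      g <- 2 * eng$k * (r - ref) * d / r
      grad[i, ] <- grad[i, ] + g
      grad[j, ] <- grad[j, ] - g
    }
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- xyz[i, ] - xyz[j, ]
      r <- vnorm(d)
      e <- e + eng$A * exp(-r / eng$rho)
      g <- -(eng$A / eng$rho) * exp(-r / eng$rho) * d / r
      grad[i, ] <- grad[i, ] + g
      grad[j, ] <- grad[j, ] - g
    }
  }
  list(energy = e, grad = grad)
}

#' @export
run_engine.toy_engine <- function(spec, engine) {
  if (spec$task == "saddle-search") {
    stop("toy engine does not support saddle searches")
  }
  s <- spec$geometry
  xyz <- atom_xyz(s)
  elements <- s$atoms$element
  bonds <- detect_bonds(s)
  frozen <- s$atoms$serial %in% spec$frozen
  if (spec$task == "minimize") {
    eg <- toy_energy_gradient(xyz, elements, bonds, engine)
    for (it in seq_len(engine$max_steps)) {
      g <- eg$grad
      g[frozen, ] <- 0
      if (max(abs(g)) < engine$tol) break
      trial <- xyz - engine$step * g
      eg2 <- toy_energy_gradient(trial, elements, bonds, engine)
      if (eg2$energy > eg$energy) break  # crude line-search stop
      xyz <- trial; eg <- eg2
    }
    s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
    qm_result(spec$job_id, eg$energy, converged = TRUE, geometry = s, n_imag = 0L)
  } else {
    e <- toy_energy_gradient(xyz, elements, bonds, engine)$energy
    qm_result(spec$job_id, e, converged = TRUE, geometry = s)
  }
}
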