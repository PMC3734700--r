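#' Gas constant in kcal/(mol K)
#' @export
R_KCAL <- 1.98720425e-3

#' Convert signed enantiomeric excess to a barrier difference
#'
#' Transition-state theory relates the product ratio of two competing
#' enantiomer-forming pathways to their barrier difference:
#' `ddG = R T ln((1 + ee) / (1 - ee))`.
#'
#' Sign convention (anchored to the calculated `barrier_C2 - barrier_C1`
#' difference): `ee > 0` means excess of the S,S product and maps to a
#' positive barrier difference; `ee < 0` (R,R excess) maps to a negative one.
#' The function is odd in `ee` and strictly monotone in both arguments.
#'
#' @param ee signed enantiomeric excess in (-1, 1) (fraction, not percent).
#' @param temperature temperature in K (default 298.15).
#' @return barrier difference in kcal/mol.
#' @export
ee_to_ddg <- function(ee, temperature = 298.15) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  if (any(abs(ee) >= 1)) stop("|ee| must be < 1 (got ", max(abs(ee)), ")")
  if (any(abs(ee) > 0.999)) {
    warning("ee beyond 99.9%: the converted barrier difference diverges",
            call. = FALSE)
  }
  R_KCAL * temperature * log((1 + ee) / (1 - ee))
}

#' Convert a barrier difference to signed enantiomeric excess
#'
#' Exact inverse of [ee_to_ddg()]: `ee = tanh(ddG / (2 R T))`, always
#' strictly inside (-1, 1).
#'
#' @param ddg barrier difference in kcal/mol (positive = S,S-favored).
#' @param temperature temperature in K.
#' @export
ddg_to_ee <- function(ddg, temperature = 298.15) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  ee <- tanh(ddg / (2 * R_KCAL * temperature))
  # keep the result strictly inside (-1, 1) even where tanh saturates
  lim <- 1 - .Machine$double.eps / 2
  pmin(pmax(ee, -lim), lim)
}

#' Boltzmann-weighted ee over transition-state ensembles
#'
#' Curtin-Hammett weighting: when several TS conformers lead to each product,
#' the product ratio follows the Boltzmann-weighted sums over each face's
#' ensemble, `ee = (W_SS - W_RR) / (W_SS + W_RR)` with
#' `W = sum_i exp(-E_i / RT)`. For one TS per face this reduces exactly to
#' `ddg_to_ee(E_RR - E_SS)`.
#'
#' Energies may be absolute or relative — any common shift cancels.
#'
#' @param ts_energies_RR,ts_energies_SS energies (kcal/mol) of the TS
#'   conformers leading to the R,R and S,S products.
#' @param temperature temperature in K.
#' @export
boltzmann_ee <- function(ts_energies_RR, ts_energies_SS, temperature = 298.15) {
  if (length(ts_energies_RR) == 0 || length(ts_energies_SS) == 0) {
    stop("each face needs at least one transition-state energy")
  }
  beta <- 1 / (R_KCAL * temperature)
  e0 <- min(ts_energies_RR, ts_energies_SS)  # log-sum-exp shift
  w_rr <- sum(exp(-beta * (ts_energies_RR - e0)))
  w_ss <- sum(exp(-beta * (ts_energies_SS - e0)))
  (w_ss - w_rr) / (w_ss + w_rr)
}

#' Selectivity record
#'
#' One variant's selectivity, carrying both representations: the signed ee
#' and the equivalent barrier difference, plus provenance.
#'
#' @param variant variant label.
#' @param ee_signed signed ee in (-1, 1); positive = S,S excess.
#' @param temperature K.
#' @param source `"experiment"` or `"calculated"`.
#' @param ddg optional barrier difference; computed from `ee_signed` when
#'   missing, and checked for sign consistency when both are given.
#' @export
selectivity_record <- function(variant, ee_signed = NULL, ddg = NULL,
                               temperature = 298.15,
                               source = c("experiment", "calculated")) {
  source <- match.arg(source)
  if (is.null(ee_signed) && is.null(ddg)) stop("need ee_signed or ddg")
  if (is.null(ddg)) ddg <- ee_to_ddg(ee_signed, temperature)
  if (is.null(ee_signed)) ee_signed <- ddg_to_ee(ddg, temperature)
  if (sign(round(ddg, 9)) * sign(round(ee_signed, 9)) < 0) {
    stop("inconsistent record for ", variant,
         ": ee and ddg disagree in sign (R,R excess must have negative ddg)")
  }
  structure(list(variant = variant, ee_signed = ee_signed, ddg = ddg,
                 temperature = temperature, source = source,
                 favored = if (ee_signed < 0) "RR" else if (ee_signed > 0) "SS" else "none"),
            class = "SelectivityRecord")
}

#' Read an experimental selectivity table
#'
#' Delimited text with a `variant` column plus either `ee_percent` and
#' `favored_product` (`RR`/`SS`) or a `ddg` column (kcal/mol); rows may use
#' either form (leave the other fields `NA`). `#` comments ignored.
#'
#' @param path path to the table.
#' @param temperature temperature used for ee -> ddg conversion, K.
#' @return list of [selectivity_record()] objects.
#' @export
read_experimental <- function(path, temperature = 298.15) {
  df <- utils::read.table(path, header = TRUE, sep = "", comment.char = "#",
                          stringsAsFactors = FALSE, na.strings = c("NA", "."))
  if (!("variant" %in% names(df))) stop("experimental table needs a 'variant' column")
  lapply(seq_len(nrow(df)), function(i) {
    if (!is.null(df$ee_percent) && !is.na(df$ee_percent[i])) {
      fav <- toupper(df$favored_product[i])
      if (!(fav %in% c("RR", "SS"))) {
        stop("favored_product must be RR or SS (variant ", df$variant[i], ")")
      }
      ee <- df$ee_percent[i] / 100 * if (fav == "RR") -1 else 1
      selectivity_record(df$variant[i], ee_signed = ee, temperature = temperature)
    } else if (!is.null(df$ddg) && !is.na(df$ddg[i])) {
      selectivity_record(df$variant[i], ddg = df$ddg[i], temperature = temperature)
    } else {
      stop("row for variant ", df$variant[i], " has neither ee_percent nor ddg")
    }
  })
}

#' Calculated-versus-experimental selectivity comparison
#'
#' Joins calculated barrier differences with experimental records and flags
#' sign agreement per variant: does the calculation put the lower barrier on
#' the same face the experiment favors? A zero on either side counts as
#' agreeing with anything. Variants present on only one side are listed in
#' the `unmatched` attribute and a summary line, never dropped silently.
#'
#' @param barrier_records data.frame from [barrier_table()] (needs `variant`
#'   and `delta_delta`).
#' @param experimental_records list of [selectivity_record()] objects.
#' @param temperature K, recorded in the summary.
#' @return data.frame with columns `variant`, `ddE_calc`, `ddG_expt`,
#'   `ee_calc`, `ee_expt`, `agree`; attributes `summary` (character) and
#'   `unmatched`.
#' @export
selectivity_report <- function(barrier_records, experimental_records,
                               temperature = 298.15) {
  expt <- data.frame(
    variant = vapply(experimental_records, function(r) r$variant, character(1)),
    ddG_expt = vapply(experimental_records, function(r) r$ddg, numeric(1)),
    ee_expt = vapply(experimental_records, function(r) r$ee_signed, numeric(1)),
    stringsAsFactors = FALSE
  )
  calc <- barrier_records[, c("variant", "delta_delta")]
  names(calc)[2] <- "ddE_calc"
  common <- intersect(calc$variant, expt$variant)
  unmatched <- union(setdiff(calc$variant, expt$variant),
                     setdiff(expt$variant, calc$variant))
  out <- merge(calc, expt, by = "variant", sort = FALSE)
  out <- out[match(intersect(calc$variant, common), out$variant), , drop = FALSE]
  if (nrow(out) > 0) {
    out$ee_calc <- ddg_to_ee(out$ddE_calc, temperature)
    out$agree <- out$ddE_calc * out$ddG_expt >= 0  # zero agrees with either
    out <- out[, c("variant", "ddE_calc", "ddG_expt", "ee_calc", "ee_expt", "agree")]
  } else {
    out <- data.frame(variant = character(0), ddE_calc = numeric(0),
                      ddG_expt = numeric(0), ee_calc = numeric(0),
                      ee_expt = numeric(0), agree = logical(0))
  }
  rownames(out) <- NULL
  summary_line <- sprintf(
    "sign agreement: %d/%d variants at T = %.2f K%s",
    sum(out$agree), nrow(out), temperature,
    if (length(unmatched) > 0)
      paste0("; unmatched: ", paste(unmatched, collapse = ", ")) else "")
  attr(out, "summary") <- summary_line
  attr(out, "unmatched") <- unmatched
  out
}
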