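#' Extraction-parameter inputs for the analytical evaluation threshold
#'
#' @param dbt Dose-based threshold, ug/day; > 0.
#' @param devices_extracted Number of devices in the extraction; > 0.
#' @param extraction_volume Extraction volume, mL; > 0.
#' @param devices_per_day Clinical devices contacting the patient per day;
#'   > 0.
#' @return A `threshold_inputs` object.
#' @export
threshold_inputs <- function(dbt, devices_extracted, extraction_volume,
                             devices_per_day) {
  stopifnot(is.numeric(dbt), dbt > 0,
            is.numeric(devices_extracted), devices_extracted > 0,
            is.numeric(extraction_volume), extraction_volume > 0,
            is.numeric(devices_per_day), devices_per_day > 0)
  structure(list(dbt = dbt, devices_extracted = devices_extracted,
                 extraction_volume = extraction_volume,
                 devices_per_day = devices_per_day),
            class = "threshold_inputs")
}

#' Derive an uncertainty factor from RRF population statistics
#'
#' The uncertainty factor (UF) converts day-of-analysis RRF variability into
#' a divisor on the analytical evaluation threshold. Strategies:
#' \describe{
#'   \item{rsd_reciprocal}{`uf = 1 / (1 - min(rsd, cap))` — the reciprocal
#'     relative-standard-deviation convention (default).}
#'   \item{percentile_ratio}{`uf = mean / p16` — the ratio of the population
#'     mean to its 16th percentile (the minus-one-sigma analogue), provided
#'     as a labeled alternative.}
#'   \item{fixed}{a supplied constant.}
#' }
#' The result is clamped to `uf >= 1` (variability never raises the
#' threshold).
#'
#' @param summary A [summarize_population()] result (needed for the RSD and
#'   percentile strategies; `n >= 2` required there).
#' @param strategy `"rsd_reciprocal"`, `"percentile_ratio"`, or `"fixed"`.
#' @param cap Ceiling applied to the RSD before the reciprocal (default 0.9);
#'   an RSD at or above 1 without a cap below 1 is degenerate and errors.
#' @param fixed_value Constant for the `"fixed"` strategy; >= 1.
#' @param source Optional label recording which population the UF came from.
#' @return A `uf_result`: list with `strategy`, `rsd`, `uf`, `source`.
#' @export
compute_uf <- function(summary = NULL,
                       strategy = c("rsd_reciprocal", "percentile_ratio",
                                    "fixed"),
                       cap = 0.9, fixed_value = NULL, source = NA_character_) {
  strategy <- match.arg(strategy)
  rsd <- NA_real_
  if (strategy == "fixed") {
    stopifnot(is.numeric(fixed_value), fixed_value >= 1)
    uf <- fixed_value
  } else {
    stopifnot(inherits(summary, "population_summary"))
    if (summary$n < 2)
      stop("population strategies need n >= 2", call. = FALSE)
    rsd <- summary$rsd
    if (strategy == "rsd_reciprocal") {
      if (rsd >= 1 && (is.null(cap) || cap >= 1))
        stop("RSD >= 1 without a cap: degenerate population", call. = FALSE)
      uf <- 1 / (1 - min(rsd, cap))
    } else {
      p16 <- summary$percentiles["p16"]
      if (p16 <= 0)
        stop("non-positive 16th percentile: degenerate population",
             call. = FALSE)
      uf <- unname(summary$mean / p16)
    }
  }
  structure(list(strategy = strategy, rsd = rsd, uf = max(1, uf),
                 source = source),
            class = "uf_result")
}

#' @export
print.uf_result <- function(x, ...) {
  cat(sprintf("<uf> %.4g  (%s%s)\n", x$uf, x$strategy,
              if (is.na(x$rsd)) "" else sprintf(", rsd=%.3f", x$rsd)))
  invisible(x)
}

#' Analytical evaluation threshold adjusted by the uncertainty factor
#'
#' The unadjusted AET follows the extraction-parameter arithmetic
#' `aet_initial = (DBT / devices_per_day) * (devices_extracted /
#' extraction_volume)` in ug/mL; the final threshold divides by the UF:
#' `aet_final = aet_initial / uf`.
#'
#' @param inputs A [threshold_inputs()].
#' @param uf A [compute_uf()] result, or a bare numeric >= 1.
#' @return A `threshold_result`: list with `aet_initial`, `uf` (the
#'   `uf_result`), `aet_final`, all concentrations in ug/mL.
#' @examples
#' compute_aet(threshold_inputs(100, 1, 100, 1),
#'             compute_uf(strategy = "fixed", fixed_value = 2))
#' @export
compute_aet <- function(inputs, uf) {
  stopifnot(inherits(inputs, "threshold_inputs"))
  if (is.numeric(uf))
    uf <- compute_uf(strategy = "fixed", fixed_value = uf)
  stopifnot(inherits(uf, "uf_result"))
  aet_initial <- (inputs$dbt / inputs$devices_per_day) *
    (inputs$devices_extracted / inputs$extraction_volume)
  structure(list(aet_initial = aet_initial, uf = uf,
                 aet_final = aet_initial / uf$uf),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<aet> initial=%.4g ug/mL  uf=%.4g  final=%.4g ug/mL\n",
              x$aet_initial, x$uf$uf, x$aet_final))
  invisible(x)
}

#' Semiquantitate a nontarget extractable through a surrogate RRF
#'
#' Converts an unknown's corrected response into a concentration using a
#' surrogate standard's RRF determined under the same quantitation model:
#' `conc = (A_nte / A_istd) * C_istd / rrf_surrogate`. The model used for the
#' unknown's response and the model behind the surrogate RRF must match —
#' mixing models re-introduces exactly the bias the workflow is designed to
#' avoid.
#'
#' @param nte_raw Unknown's raw response (area) under `model`.
#' @param istd_raw Internal-standard raw response in the same sample; > 0.
#' @param istd_conc Internal-standard spiked concentration, ug/mL.
#' @param surrogate An accepted `rrf_estimate` (or a row of [rrf_table()])
#'   for the surrogate under `model`.
#' @param model [quant_model()] (or its `format()` label) used for
#'   `nte_raw`.
#' @param surrogate_model Label of the model behind `surrogate` when
#'   `surrogate` is a bare list without one.
#' @param true_conc Optional known concentration (simulation truth), for the
#'   relative bias.
#' @param nte_id,surrogate_id Identifiers carried into the result.
#' @return An `nte_quant`: list with `nte_id`, `surrogate_id`, `model`,
#'   `corrected`, `conc` (ug/mL), `true_conc`, `bias` (fraction, `NA`
#'   without truth).
#' @export
semiquantitate <- function(nte_raw, istd_raw, istd_conc, surrogate, model,
                           surrogate_model = NULL, true_conc = NA_real_,
                           nte_id = "unknown", surrogate_id = NA_character_) {
  model_lab <- if (inherits(model, "quant_model")) format(model) else model
  if (is.data.frame(surrogate)) {
    stopifnot(nrow(surrogate) == 1L)
    surrogate <- as.list(surrogate)
    surrogate_model <- surrogate$model
    if (is.na(surrogate_id)) surrogate_id <- surrogate$compound_id
  }
  if (inherits(surrogate, "rrf_estimate") || is.list(surrogate)) {
    if (!isTRUE(surrogate$accepted))
      stop("surrogate RRF estimate was not accepted", call. = FALSE)
    if (!is.null(surrogate$model)) surrogate_model <- surrogate$model
    rrf <- surrogate$rrf
  } else {
    rrf <- surrogate
  }
  if (!is.null(surrogate_model) &&
      !identical(model_kind(model_lab), model_kind(surrogate_model)))
    stop("quantitation model mismatch: unknown quantified with ", model_lab,
         " but surrogate RRF is ", surrogate_model, call. = FALSE)
  stopifnot(is.numeric(rrf), rrf > 0, istd_conc > 0)
  corrected <- istd_correct(nte_raw, istd_raw)
  conc <- corrected * istd_conc / rrf
  structure(list(nte_id = nte_id, surrogate_id = surrogate_id,
                 model = model_lab, corrected = corrected, conc = conc,
                 true_conc = true_conc,
                 bias = if (is.na(true_conc)) NA_real_
                        else (conc - true_conc) / true_conc),
            class = "nte_quant")
}

# model labels carry EIC selections, e.g. "EIC_single([M+H]+,iso0)"; the
# consistency requirement is on the model kind
model_kind <- function(label) sub("\\(.*$", "", label)

#' @export
print.nte_quant <- function(x, ...) {
  cat(sprintf("<nte_quant> %s via %s (%s): %.4g ug/mL%s\n",
              x$nte_id, x$surrogate_id, x$model, x$conc,
              if (is.na(x$bias)) "" else sprintf("  bias=%+.1f%%",
                                                 100 * x$bias)))
  invisible(x)
}

#' Reportable subset of semiquantitated unknowns
#'
#' Filters semiquantitated concentrations against the UF-adjusted AET. The
#' comparison is inclusive (`conc >= aet_final`): a compound exactly at the
#' threshold is reported, the protective reading of "above which all
#' extractables must be identified and quantified".
#'
#' @param results List of `nte_quant` objects, or a data frame with a `conc`
#'   column.
#' @param threshold A `threshold_result` from [compute_aet()].
#' @return Data frame of the reportable rows (`nte_id`, `surrogate_id`,
#'   `model`, `conc`, `true_conc`, `bias`), ordered by concentration
#'   descending, with attribute `n_total` (input count).
#' @export
reportable_set <- function(results, threshold) {
  stopifnot(inherits(threshold, "threshold_result"))
  if (is.data.frame(results)) {
    tab <- results
  } else {
    tab <- do.call(rbind, lapply(results, function(r)
      data.frame(nte_id = r$nte_id, surrogate_id = r$surrogate_id,
                 model = r$model, conc = r$conc, true_conc = r$true_conc,
                 bias = r$bias)))
  }
  keep <- tab[tab$conc >= threshold$aet_final, , drop = FALSE]
  keep <- keep[order(-keep$conc), , drop = FALSE]
  rownames(keep) <- NULL
  attr(keep, "n_total") <- nrow(tab)
  keep
}
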