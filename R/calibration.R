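#' Data-acceptance criteria for a calibration range
#'
#' System-reproducibility and linearity filters applied before an RRF is
#' trusted: replicate-injection RSD below a ceiling, and a weighted-fit
#' coefficient of determination above a floor under the technique's required
#' weighting (1/x^2 for GCMS with R^2 > 0.95; 1/x for LCMS with R^2 > 0.97).
#'
#' @param technique `"GCMS"`, `"LCMS_pos"`, or `"LCMS_neg"` (sets defaults),
#'   or `NULL` to give all three fields explicitly.
#' @param max_injection_rsd Maximum per-level replicate RSD (fraction).
#' @param min_r_squared Minimum weighted R^2.
#' @param weighting Required fit weighting: `"none"`, `"inv_x"`, `"inv_x2"`.
#' @return An `acceptance_criteria` object.
#' @export
acceptance_criteria <- function(technique = NULL,
                                max_injection_rsd = 0.20,
                                min_r_squared = NULL,
                                weighting = NULL) {
  if (!is.null(technique)) {
    technique <- match.arg(technique, c("GCMS", "LCMS_pos", "LCMS_neg"))
    if (is.null(min_r_squared))
      min_r_squared <- if (technique == "GCMS") 0.95 else 0.97
    if (is.null(weighting))
      weighting <- if (technique == "GCMS") "inv_x2" else "inv_x"
  }
  if (is.null(min_r_squared) || is.null(weighting))
    stop("give a technique or explicit min_r_squared and weighting",
         call. = FALSE)
  weighting <- match.arg(weighting, c("none", "inv_x", "inv_x2"))
  stopifnot(max_injection_rsd > 0, max_injection_rsd <= 1,
            min_r_squared > 0, min_r_squared <= 1)
  structure(list(max_injection_rsd = max_injection_rsd,
                 min_r_squared = min_r_squared, weighting = weighting),
            class = "acceptance_criteria")
}

#' Single-point relative response factor
#'
#' RRF at one concentration: the analyte's concentration-normalized response
#' over the internal standard's, expressed through the corrected response
#' ratio as `corrected * C_istd / C_analyte`.
#'
#' @param corrected Internal-standard-corrected response (analyte area /
#'   ISTD area), >= 0.
#' @param conc_analyte Analyte concentration, ug/mL; > 0.
#' @param conc_istd Internal-standard concentration, ug/mL; > 0.
#' @return Dimensionless RRF.
#' @export
rrf_single_point <- function(corrected, conc_analyte, conc_istd) {
  stopifnot(is.numeric(corrected), all(corrected >= 0))
  if (any(conc_analyte <= 0) || any(conc_istd <= 0))
    stop("concentrations must be > 0", call. = FALSE)
  corrected * conc_istd / conc_analyte
}

#' Weighted linear least-squares fit
#'
#' Fits `y = a + b x` minimizing `sum(w (y - a - b x)^2)` with the
#' calibration weightings in common use: `none` (w = 1), `inv_x` (w = 1/x),
#' `inv_x2` (w = 1/x^2). The coefficient of determination is the weighted
#' R^2 (weighted residual sum of squares about the weighted mean).
#'
#' @param x Concentrations; at least two distinct values, > 0 for the
#'   inverse weightings.
#' @param y Responses (same length).
#' @param weighting `"none"`, `"inv_x"`, or `"inv_x2"`.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
weighted_linear_fit <- function(x, y, weighting = c("none", "inv_x",
                                                    "inv_x2")) {
  weighting <- match.arg(weighting)
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(unique(x)) < 2)
    stop("all x identical: cannot fit a slope", call. = FALSE)
  w <- switch(weighting,
              none = rep(1, length(x)),
              inv_x = { if (any(x <= 0))
                stop("inverse weighting needs x > 0", call. = FALSE)
                1 / x },
              inv_x2 = { if (any(x <= 0))
                stop("inverse weighting needs x > 0", call. = FALSE)
                1 / x^2 })
  fit <- stats::lm(y ~ x, weights = w)
  yhat <- stats::fitted(fit)
  ybar <- sum(w * y) / sum(w)
  ss_res <- sum(w * (y - yhat)^2)
  ss_tot <- sum(w * (y - ybar)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

# per-level replicate summary of a responses table for one run/compound/model
level_summary <- function(responses, design) {
  d <- merge(responses, design[, c("run_id", "sample_id", "compound_id",
                                   "true_conc", "istd_conc")],
             by = c("run_id", "sample_id", "compound_id"))
  agg <- stats::aggregate(corrected ~ true_conc, data = d,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(conc = agg$true_conc,
                    mean = agg$corrected[, "mean"],
                    sd = agg$corrected[, "sd"],
                    n = agg$corrected[, "n"])
  out$rsd <- ifelse(out$n > 1 & out$mean > 0, out$sd / out$mean, 0)
  out[order(out$conc), ]
}

#' RRF from the slope of a qualified dynamic range
#'
#' Averages replicate injections per level (retaining the per-level injection
#' RSD as a diagnostic), fits a weighted least-squares line of corrected
#' response against concentration over the levels inside `range`, and scales
#' the slope by the internal-standard concentration so the estimate matches
#' the single-point RRF convention when the line passes through the origin.
#'
#' @param responses Responses for one (run, compound, model) — rows from
#'   [quantify_features()] with non-missing `corrected`.
#' @param design Calibration design rows covering those samples.
#' @param range Length-2 numeric `(low, high)` ug/mL; levels with
#'   `low <= conc <= high` enter the fit.
#' @param weighting Fit weighting (see [weighted_linear_fit()]).
#' @param criteria Optional [acceptance_criteria()]; when given, the estimate
#'   is evaluated with [apply_acceptance()].
#' @return An `rrf_estimate`: list with `rrf`, `method = "slope"`,
#'   `weighting`, `range`, `slope`, `intercept`, `r_squared`, `n_levels`,
#'   `injection_rsd_max`, `accepted`, `rejection_reason`.
#' @export
rrf_from_slope <- function(responses, design, range, weighting = "none",
                           criteria = NULL) {
  stopifnot(length(range) == 2, range[1] < range[2])
  lv <- level_summary(responses, design)
  istd_conc <- unique(stats::na.omit(
    design$istd_conc[design$compound_id %in% responses$compound_id]))
  if (length(istd_conc) != 1L)
    stop("internal-standard concentration not unique for the series",
         call. = FALSE)
  inr <- lv[lv$conc >= range[1] & lv$conc <= range[2], , drop = FALSE]
  est <- list(rrf = NA_real_, method = "slope", weighting = weighting,
              range = as.numeric(range), slope = NA_real_,
              intercept = NA_real_, r_squared = NA_real_,
              n_levels = nrow(inr),
              injection_rsd_max = if (nrow(inr)) max(inr$rsd) else NA_real_,
              accepted = FALSE, rejection_reason = NA_character_)
  class(est) <- "rrf_estimate"
  if (nrow(inr) < 2L) {
    est$rejection_reason <- "insufficient levels"
    return(est)
  }
  fit <- weighted_linear_fit(inr$conc, inr$mean, weighting)
  est$slope <- fit$slope
  est$intercept <- fit$intercept
  est$r_squared <- fit$r_squared
  est$rrf <- fit$slope * istd_conc
  est$accepted <- TRUE
  if (!is.null(criteria)) est <- apply_acceptance(est, criteria)
  est
}

#' @export
print.rrf_estimate <- function(x, ...) {
  cat(sprintf("<rrf_estimate> rrf=%.4g  %s/%s  range=[%g,%g]  R2=%.4f  %s\n",
              x$rrf, x$method, x$weighting, x$range[1], x$range[2],
              x$r_squared,
              if (isTRUE(x$accepted)) "accepted"
              else paste("rejected:", x$rejection_reason)))
  invisible(x)
}

#' Apply data-acceptance criteria to an RRF estimate
#'
#' An estimate is accepted only if its worst per-level injection RSD is below
#' the ceiling and its weighted R^2, obtained under the required weighting,
#' clears the floor. Failures record the reason; both failing records both
#' reasons.
#'
#' @param estimate An `rrf_estimate` from [rrf_from_slope()].
#' @param criteria An [acceptance_criteria()].
#' @return The estimate with `accepted` and `rejection_reason` set.
#' @export
apply_acceptance <- function(estimate, criteria) {
  stopifnot(inherits(estimate, "rrf_estimate"),
            inherits(criteria, "acceptance_criteria"))
  reasons <- character(0)
  if (!is.na(estimate$rejection_reason) &&
      estimate$rejection_reason == "insufficient levels") {
    estimate$accepted <- FALSE
    return(estimate)
  }
  if (!identical(estimate$weighting, criteria$weighting))
    reasons <- c(reasons, sprintf("weighting %s != required %s",
                                  estimate$weighting, criteria$weighting))
  if (!is.na(estimate$injection_rsd_max) &&
      estimate$injection_rsd_max >= criteria$max_injection_rsd)
    reasons <- c(reasons, "injection RSD")
  if (is.na(estimate$r_squared) ||
      estimate$r_squared <= criteria$min_r_squared)
    reasons <- c(reasons, "r_squared")
  estimate$accepted <- length(reasons) == 0L
  estimate$rejection_reason <- if (length(reasons))
    paste(reasons, collapse = "; ") else NA_character_
  estimate
}

#' Build the per-run RRF table for a campaign
#'
#' Runs [rrf_from_slope()] for every (run, compound, model) series in a
#' responses table, under one dynamic range and the technique's acceptance
#' criteria. Internal standards (no `istd_id` in the design) are skipped.
#'
#' @param responses Output of [quantify_features()].
#' @param design Campaign calibration design.
#' @param range Dynamic range `(low, high)` ug/mL.
#' @param criteria [acceptance_criteria()] (its `weighting` is used for the
#'   fit).
#' @return Data frame `rrf_table`: `run_id`, `compound_id`, `model`,
#'   `method`, `weighting`, `range_low`, `range_high`, `rrf`, `r_squared`,
#'   `n_levels`, `injection_rsd_max`, `accepted`, `rejection_reason`.
#' @export
rrf_table <- function(responses, design, range, criteria) {
  stopifnot(inherits(criteria, "acceptance_criteria"))
  analytes <- unique(design$compound_id[!is.na(design$istd_id)])
  combos <- unique(responses[responses$compound_id %in% analytes,
                             c("run_id", "compound_id", "model")])
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sel <- responses$run_id == combos$run_id[i] &
      responses$compound_id == combos$compound_id[i] &
      responses$model == combos$model[i]
    est <- rrf_from_slope(responses[sel, , drop = FALSE], design, range,
                          weighting = criteria$weighting,
                          criteria = criteria)
    rows[[i]] <- data.frame(
      run_id = combos$run_id[i], compound_id = combos$compound_id[i],
      model = combos$model[i], method = est$method,
      weighting = est$weighting, range_low = est$range[1],
      range_high = est$range[2], rrf = est$rrf, r_squared = est$r_squared,
      n_levels = est$n_levels, injection_rsd_max = est$injection_rsd_max,
      accepted = est$accepted, rejection_reason = est$rejection_reason)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
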