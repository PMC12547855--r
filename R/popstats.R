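#' Extract an RRF population from an RRF table
#'
#' Collects one compound's per-run RRFs (one value per instrumental
#' calibration) under one quantitation model, by default restricted to
#' estimates that passed the data-acceptance filters.
#'
#' @param rrf_tab Output of [rrf_table()].
#' @param compound_id Compound to extract.
#' @param model Quantitation model label (as stored in the table); `NULL` if
#'   the table holds a single model.
#' @param accepted_only Keep only accepted estimates (default `TRUE`).
#' @return An `rrf_population`: list with `compound_id`, `model`, `values`,
#'   `run_ids`.
#' @export
rrf_population <- function(rrf_tab, compound_id, model = NULL,
                           accepted_only = TRUE) {
  sel <- rrf_tab$compound_id == compound_id
  if (!is.null(model)) sel <- sel & rrf_tab$model == model
  if (accepted_only) sel <- sel & rrf_tab$accepted
  sel <- sel & !is.na(rrf_tab$rrf)
  sub <- rrf_tab[sel, , drop = FALSE]
  if (anyDuplicated(sub$run_id))
    stop("more than one RRF per run for ", compound_id,
         "; filter the table to one method/range first", call. = FALSE)
  structure(list(compound_id = compound_id,
                 model = if (is.null(model)) unique(sub$model) else model,
                 values = sub$rrf, run_ids = sub$run_id),
            class = "rrf_population")
}

#' Summarize an RRF population
#'
#' Sample moments and order statistics of a compound's per-run RRFs: n, mean,
#' sample (n-1) standard deviation, RSD (sd/mean), and percentiles by linear
#' interpolation between order statistics (including the median and the 16th
#' and 84th percentiles, the +/- one-sigma analogues used when response-factor
#' distributions are compared).
#'
#' @param pop An `rrf_population`, or a bare numeric vector of RRFs.
#' @return A `population_summary`: list with `n`, `mean`, `sd`, `rsd`, `min`,
#'   `max`, and `percentiles` (named vector: p2.5, p16, p50, p84, p97.5).
#' @export
summarize_population <- function(pop) {
  values <- if (inherits(pop, "rrf_population")) pop$values else pop
  if (length(values) == 0L) stop("empty population", call. = FALSE)
  stopifnot(is.numeric(values), all(is.finite(values)))
  qs <- stats::quantile(values, c(0.025, 0.16, 0.5, 0.84, 0.975),
                        type = 7, names = FALSE)
  names(qs) <- c("p2.5", "p16", "p50", "p84", "p97.5")
  m <- mean(values)
  s <- if (length(values) > 1L) stats::sd(values) else 0
  structure(list(n = length(values), mean = m, sd = s,
                 rsd = if (m > 0) s / m else NA_real_,
                 min = min(values), max = max(values), percentiles = qs),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf(
    "<population_summary> n=%d  mean=%.4g  sd=%.4g  rsd=%.3f  p50=%.4g  p84=%.4g\n",
    x$n, x$mean, x$sd, x$rsd, x$percentiles["p50"], x$percentiles["p84"]))
  invisible(x)
}

#' Welch's unequal-variance t-test between two RRF populations
#'
#' Two-tailed Welch t-test with Welch-Satterthwaite degrees of freedom, the
#' comparison used to show that compounds — even close structural neighbours —
#' carry different RRF population means and variances across calibrations.
#'
#' @param a,b Numeric vectors (each n >= 2; at least one with positive
#'   variance).
#' @param alpha Significance level recorded with the result.
#' @return A `welch_result`: list with `t`, `df` (real-valued), `p`
#'   (two-tailed), `alpha`, `significant`.
#' @export
welch_test <- function(a, b, alpha = 0.05) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("both groups have zero variance", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, alpha = alpha,
                 significant = ht$p.value < alpha),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("<welch> t=%.4g  df=%.2f  p=%.3g  %s at alpha=%g\n",
              x$t, x$df, x$p,
              if (x$significant) "significant" else "not significant",
              x$alpha))
  invisible(x)
}

#' Brown-Forsythe (Levene-type) test for unequal variances
#'
#' Classic one-way ANOVA F-test on absolute deviations from each group's
#' median — robust to non-normality, which matters for lognormal-like RRF
#' populations.
#'
#' @param a,b Numeric vectors, each n >= 2.
#' @param alpha Significance level recorded with the result.
#' @return List with `F`, `df1`, `df2`, `p`, `alpha`, `significant`.
#' @export
levene_test <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  dev <- c(abs(a - stats::median(a)), abs(b - stats::median(b)))
  grp <- factor(rep(c("a", "b"), c(length(a), length(b))))
  fit <- stats::anova(stats::lm(dev ~ grp))
  list(F = fit$`F value`[1], df1 = fit$Df[1], df2 = fit$Df[2],
       p = fit$`Pr(>F)`[1], alpha = alpha,
       significant = fit$`Pr(>F)`[1] < alpha)
}

#' Pairwise variance-inequality report across RRF populations
#'
#' For every pair of populations, reports the ratio of RSDs, the Welch test
#' on means, and the Brown-Forsythe test on spreads — the evidence that RRF
#' location and variability are unequal across the monitored chemical space,
#' so a single pooled variability understates some compounds. p-values are
#' raw (unadjusted), as flagged in the output.
#'
#' @param populations Named list of numeric vectors or `rrf_population`s
#'   (>= 2 entries).
#' @param alpha Significance level.
#' @return Data frame: `a`, `b`, `n_a`, `n_b`, `rsd_a`, `rsd_b`,
#'   `rsd_ratio`, `t`, `df`, `p`, `significant`, `levene_F`, `levene_p`,
#'   `levene_significant`, `p_adjusted` (= "none").
#' @export
variance_inequality_report <- function(populations, alpha = 0.05) {
  if (length(populations) < 2L)
    stop("need at least two populations", call. = FALSE)
  vals <- lapply(populations, function(p)
    if (inherits(p, "rrf_population")) p$values else p)
  nm <- names(vals)
  if (is.null(nm)) nm <- paste0("pop", seq_along(vals))
  pairs <- utils::combn(seq_along(vals), 2)
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    sa <- summarize_population(vals[[i]])
    sb <- summarize_population(vals[[j]])
    wt <- welch_test(vals[[i]], vals[[j]], alpha)
    lv <- levene_test(vals[[i]], vals[[j]], alpha)
    rows[[k]] <- data.frame(a = nm[i], b = nm[j], n_a = sa$n, n_b = sb$n,
                            rsd_a = sa$rsd, rsd_b = sb$rsd,
                            rsd_ratio = sa$rsd / sb$rsd,
                            t = wt$t, df = wt$df, p = wt$p,
                            significant = wt$significant,
                            levene_F = lv$F, levene_p = lv$p,
                            levene_significant = lv$significant,
                            p_adjusted = "none")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
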