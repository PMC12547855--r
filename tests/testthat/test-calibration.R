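# hand-made responses/design for one run, one compound, one model
make_series <- function(levels, reps, istd_conc = 1, compound = "cmp",
                        model = "ECC") {
  stopifnot(length(reps) == length(levels))
  rows <- list()
  for (i in seq_along(levels)) {
    for (j in seq_along(reps[[i]])) {
      rows[[length(rows) + 1]] <- data.frame(
        run_id = "run001", sample_id = sprintf("L%02d_I%02d", i, j),
        compound_id = compound, model = model, raw = NA_real_,
        istd_id = "istd", istd_raw = 1, corrected = reps[[i]][j])
    }
  }
  resp <- do.call(rbind, rows)
  design <- unique(data.frame(run_id = "run001",
                              sample_id = resp$sample_id,
                              compound_id = compound,
                              true_conc = rep(levels,
                                              vapply(reps, length,
                                                     integer(1))),
                              istd_id = "istd", istd_conc = istd_conc))
  list(responses = resp, design = design)
}

test_that("single-point RRF is the concentration-normalized area ratio", {
  expect_equal(rrf_single_point(1.0, 1, 1), 1.0)
  expect_equal(rrf_single_point(2.0, 1, 0.5), 1.0)
  expect_equal(rrf_single_point(0.16 * 10 / 0.5, 10, 0.5), 0.16)
  expect_error(rrf_single_point(1, 0, 1), "> 0")
})

test_that("weighted fits equal the closed-form normal equations", {
  # hand-solved 2x2 normal equations for three points under 1/x weighting
  x <- c(1, 2, 4); y <- c(1, 2.2, 3.6)
  got <- weighted_linear_fit(x, y, "inv_x")
  want <- oracle_wls(x, y, 1 / x)
  expect_equal(got$slope, want$slope, tolerance = 1e-12)
  expect_equal(got$intercept, want$intercept, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    x <- sort(runif(n, 0.1, 10))
    y <- 2 * x + rnorm(n, 0, 0.3)
    for (wt in c("none", "inv_x", "inv_x2")) {
      w <- switch(wt, none = rep(1, n), inv_x = 1 / x, inv_x2 = 1 / x^2)
      got <- weighted_linear_fit(x, y, wt)
      want <- oracle_wls(x, y, w)
      expect_equal(got$slope, want$slope, tolerance = 1e-10)
      expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
    }
  }
})

test_that("a perfect line is invariant to weighting and subrange", {
  x <- c(0.1, 0.5, 1, 5); y <- 2 * x
  for (wt in c("none", "inv_x", "inv_x2")) {
    fit <- weighted_linear_fit(x, y, wt)
    expect_equal(fit$slope, 2, tolerance = 1e-12)
    expect_equal(fit$intercept, 0, tolerance = 1e-12)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  }
  expect_error(weighted_linear_fit(c(1, 1), c(1, 2), "none"),
               "all x identical")
  expect_error(weighted_linear_fit(c(-1, 2), c(1, 2), "inv_x"), "x > 0")
})

test_that("inverse weighting pulls curved fits toward the low end", {
  # concave (saturating) data: low points up-weighted raises the slope
  x <- c(0.5, 1, 2, 5, 10)
  y <- x / (1 + 0.4 * x)
  s_none <- weighted_linear_fit(x, y, "none")$slope
  s_w2 <- weighted_linear_fit(x, y, "inv_x2")$slope
  expect_gt(s_w2, s_none)
})

test_that("slope RRF is subrange-independent on a noiseless line", {
  lv <- c(0.025, 0.05, 0.1, 0.25, 0.5, 1)
  ser <- make_series(lv, lapply(2 * lv, rep, 3), istd_conc = 0.1)
  r_full <- rrf_from_slope(ser$responses, ser$design, c(0.02, 1), "inv_x")
  r_low <- rrf_from_slope(ser$responses, ser$design, c(0.02, 0.11), "inv_x")
  r_high <- rrf_from_slope(ser$responses, ser$design, c(0.2, 1), "inv_x")
  expect_equal(r_full$rrf, 2 * 0.1, tolerance = 1e-10)
  expect_equal(r_low$rrf, r_full$rrf, tolerance = 1e-10)
  expect_equal(r_high$rrf, r_full$rrf, tolerance = 1e-10)
  # and it matches the single-point convention for an origin line
  expect_equal(r_full$rrf, rrf_single_point(2 * 0.5, 0.5, 0.1),
               tolerance = 1e-10)
})

test_that("too few in-range levels reject with a reason, never error", {
  lv <- c(0.1, 1)
  ser <- make_series(lv, lapply(2 * lv, rep, 2))
  est <- rrf_from_slope(ser$responses, ser$design, c(5, 10), "none")
  expect_false(est$accepted)
  expect_match(est$rejection_reason, "insufficient levels")
  est2 <- rrf_from_slope(ser$responses, ser$design, c(5, 10), "none",
                         criteria = acceptance_criteria("GCMS",
                                                        weighting = "none"))
  expect_false(est2$accepted)
})

test_that("acceptance filters reject high injection RSD and weak linearity", {
  # replicate RSD of 25% at one level: reproducibility failure
  lv <- c(0.1, 0.5, 1)
  reps <- list(c(0.2, 0.2, 0.2), c(0.75, 1.0, 1.25), c(2, 2, 2))
  rsd <- sd(reps[[2]]) / mean(reps[[2]])
  expect_equal(rsd, 0.25)
  ser <- make_series(lv, reps)
  est <- rrf_from_slope(ser$responses, ser$design, c(0.05, 1), "inv_x",
                        criteria = acceptance_criteria("LCMS_pos"))
  expect_false(est$accepted)
  expect_match(est$rejection_reason, "injection RSD")

  crit_gc <- acceptance_criteria("GCMS")
  crit_lc <- acceptance_criteria("LCMS_pos")
  mk <- function(r2, w) structure(
    list(rrf = 1, method = "slope", weighting = w, range = c(0.1, 1),
         slope = 1, intercept = 0, r_squared = r2, n_levels = 5,
         injection_rsd_max = 0.05, accepted = TRUE,
         rejection_reason = NA_character_), class = "rrf_estimate")
  # GCMS: R2 above 0.95 with 1/x2 passes; LCMS needs 0.97 with 1/x
  expect_true(apply_acceptance(mk(0.96, "inv_x2"), crit_gc)$accepted)
  expect_false(apply_acceptance(mk(0.96, "inv_x"), crit_lc)$accepted)
  expect_match(apply_acceptance(mk(0.96, "inv_x"), crit_lc)$rejection_reason,
               "r_squared")
  expect_true(apply_acceptance(mk(0.975, "inv_x"), crit_lc)$accepted)
  # boundary: exactly at the floor is not above it
  expect_false(apply_acceptance(mk(0.95, "inv_x2"), crit_gc)$accepted)
  # wrong weighting is itself a rejection
  expect_false(apply_acceptance(mk(0.99, "none"), crit_gc)$accepted)
})

test_that("tightening criteria never turns a rejection into acceptance", {
  mk <- function(rsd, r2) structure(
    list(rrf = 1, method = "slope", weighting = "inv_x", range = c(0.1, 1),
         slope = 1, intercept = 0, r_squared = r2, n_levels = 5,
         injection_rsd_max = rsd, accepted = TRUE,
         rejection_reason = NA_character_), class = "rrf_estimate")
  set.seed(13)
  for (i in 1:30) {
    est <- mk(runif(1, 0, 0.4), runif(1, 0.9, 1))
    loose <- acceptance_criteria(max_injection_rsd = 0.3,
                                 min_r_squared = 0.95, weighting = "inv_x")
    tight <- acceptance_criteria(max_injection_rsd = 0.2,
                                 min_r_squared = 0.97, weighting = "inv_x")
    a_loose <- apply_acceptance(est, loose)$accepted
    a_tight <- apply_acceptance(est, tight)$accepted
    expect_true(!a_tight || a_loose)
  }
})

test_that("slope RRFs recover the simulator's truth", {
  camp <- tiny_lc_campaign(seed = 21, noise_cv = 0.05, dispersion = 0)
  resp <- quantify_features(camp$features, camp$design, models = list("ECC"))
  tab <- rrf_table(resp, camp$design, c(0.02, 1),
                   acceptance_criteria("LCMS_pos"))
  # truth: coef_analyte / coef_istd = 2
  expect_equal(tab$rrf, 2, tolerance = 0.1)
  expect_true(all(tab$accepted))
})
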