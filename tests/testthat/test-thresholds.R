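mk_summary <- function(values) summarize_population(values)

test_that("uncertainty factors follow their strategy closed forms", {
  s0 <- mk_summary(c(2, 2, 2))                 # rsd 0
  expect_equal(compute_uf(s0)$uf, 1)
  expect_equal(compute_uf(s0, strategy = "percentile_ratio")$uf, 1)

  # rsd 0.5 -> 1 / (1 - 0.5) = 2
  s <- structure(list(n = 10, mean = 1, sd = 0.5, rsd = 0.5, min = 0.3,
                      max = 2, percentiles = c(p2.5 = 0.4, p16 = 0.5,
                                               p50 = 1, p84 = 1.6,
                                               p97.5 = 1.9)),
                 class = "population_summary")
  expect_equal(compute_uf(s)$uf, 2)
  # rsd 0.9 capped at 0.8 -> 5
  s$rsd <- 0.9
  expect_equal(compute_uf(s, cap = 0.8)$uf, 5)
  # rsd at or above 1 is only usable with a cap below 1
  s$rsd <- 1.2
  expect_error(compute_uf(s, cap = 1), "degenerate")
  expect_equal(compute_uf(s, cap = 0.8)$uf, 5)
  # percentile strategy: mean over its 16th percentile
  s$rsd <- 0.5
  expect_equal(compute_uf(s, strategy = "percentile_ratio")$uf, 1 / 0.5)
  expect_equal(compute_uf(strategy = "fixed", fixed_value = 3)$uf, 3)
  expect_error(compute_uf(strategy = "fixed", fixed_value = 0.5))
})

test_that("AET arithmetic follows the extraction parameters and the UF", {
  t1 <- compute_aet(threshold_inputs(100, 1, 100, 1), 1)
  expect_equal(t1$aet_initial, 1.0)
  expect_equal(t1$aet_final, 1.0)
  t2 <- compute_aet(threshold_inputs(100, 1, 100, 1), 2)
  expect_equal(t2$aet_final, 0.5)
  t3 <- compute_aet(threshold_inputs(1.5, 10, 500, 1), 3)
  expect_equal(t3$aet_initial, 0.03)
  expect_equal(t3$aet_final, 0.01)
  expect_error(threshold_inputs(100, 1, 0, 1))
})

test_that("aet_final decreases in UF and reportable counts never shrink", {
  set.seed(23)
  for (i in 1:10) {
    inputs <- threshold_inputs(runif(1, 1, 200), sample(1:20, 1),
                               runif(1, 10, 1000), sample(1:3, 1))
    ufs <- sort(runif(5, 1, 8))
    aets <- vapply(ufs, function(u) compute_aet(inputs, u)$aet_final,
                   numeric(1))
    expect_true(all(diff(aets) < 0))
    concs <- data.frame(nte_id = paste0("n", 1:30),
                        surrogate_id = "s", model = "ECC",
                        conc = rlnorm(30, log(aets[3]), 1),
                        true_conc = NA_real_, bias = NA_real_)
    counts <- vapply(ufs, function(u)
      nrow(reportable_set(concs, compute_aet(inputs, u))), numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
  # linear in the dose-based threshold
  a1 <- compute_aet(threshold_inputs(10, 2, 100, 1), 2)$aet_final
  a2 <- compute_aet(threshold_inputs(30, 2, 100, 1), 2)$aet_final
  expect_equal(a2, 3 * a1)
})

test_that("the reportable boundary is inclusive and ordered", {
  th <- compute_aet(threshold_inputs(100, 1, 100, 1), 2)  # aet_final 0.5
  tab <- data.frame(nte_id = c("lo", "at", "hi"), surrogate_id = "s",
                    model = "ECC", conc = c(0.49, 0.5, 1.2),
                    true_conc = NA_real_, bias = NA_real_)
  rep <- reportable_set(tab, th)
  expect_equal(rep$nte_id, c("hi", "at"))   # descending, boundary included
  expect_equal(attr(rep, "n_total"), 3)
  none <- reportable_set(tab[tab$conc < 0.5, , drop = FALSE], th)
  expect_equal(nrow(none), 0)
})

test_that("semiquantitation converts corrected response through the surrogate RRF", {
  expect_equal(semiquantitate(50, 100, 1, 0.5, "ECC")$conc, 1.0)
  r <- semiquantitate(50, 100, 1, 0.5, "ECC", true_conc = 0.8)
  expect_equal(r$bias, (1 - 0.8) / 0.8)
  est <- structure(list(rrf = 2, accepted = TRUE), class = "rrf_estimate")
  expect_equal(semiquantitate(100, 100, 1, est, "ECC")$conc, 0.5)
  bad <- structure(list(rrf = 2, accepted = FALSE), class = "rrf_estimate")
  expect_error(semiquantitate(100, 100, 1, bad, "ECC"), "not accepted")
  expect_error(semiquantitate(100, 100, 1, 0.5, "ECC",
                              surrogate_model = "EIC_single"),
               "model mismatch")
  # matching kinds with different selections are consistent
  expect_silent(semiquantitate(100, 100, 1, 0.5, "EIC_single([M+H]+,iso0)",
                               surrogate_model = "EIC_single(frag:57,iso0)"))
})

test_that("self-quantitation is unbiased and single-ion cross-quantitation is not", {
  camp <- tiny_lc_campaign(seed = 14, noise_cv = 0, dispersion = 0)
  resp <- quantify_features(camp$features, camp$design, models = list("ECC"))
  tab <- rrf_table(resp, camp$design, c(0.02, 1),
                   acceptance_criteria("LCMS_pos", weighting = "inv_x"))
  surr <- tab[1, ]
  nte <- compound_spec("nte", "C12H20O7", "LCMS_pos", 2e5,
                       adducts = c("[M+H]+" = 0.6, "[M+Na]+" = 0.4),
                       dispersion = 0, istd_id = "istd")
  s <- simulate_nte_sample(nte, 0.15, camp, "run001")
  unk <- s$features[s$features$compound_id == "unknown", ]
  istd_rows <- s$features[s$features$compound_id == "istd", ]
  r <- semiquantitate(compute_response(unk, quant_model("ECC")),
                      compute_response(istd_rows, quant_model("ECC")),
                      camp$truth$config$istd_conc, surr, "ECC",
                      true_conc = 0.15)
  expect_equal(r$bias, 0, tolerance = 1e-9)
})
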