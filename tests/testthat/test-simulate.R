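test_that("compound and campaign constructors enforce their invariants", {
  expect_error(compound_spec("x", "C2H6O", "LCMS_pos", 1e5,
                             adducts = c("[M+H]+" = 0.5)),
               "sum to 1")
  expect_error(compound_spec("x", "C2H6O", "LCMS_pos", 1e5,
                             adducts = c("[M-H]-" = 1)),
               "polarity")
  expect_error(compound_spec("x", "C2H6O", "GCMS", 1e5), "fragmentation")
  expect_error(campaign_config(runs = 1, levels = c(1, 0.5)))
  expect_error(campaign_config(runs = 0, levels = 1))
  expect_error(simulate_campaign(list(), campaign_config(1, 1)), "empty")
})

test_that("a fixed seed reproduces the campaign exactly", {
  c1 <- tiny_lc_campaign(seed = 11, runs = 3, adduct_drift = 50)
  c2 <- tiny_lc_campaign(seed = 11, runs = 3, adduct_drift = 50)
  expect_identical(c1$features, c2$features)
  expect_identical(c1$design, c2$design)
  c3 <- tiny_lc_campaign(seed = 12, runs = 3, adduct_drift = 50)
  expect_false(identical(c1$features, c3$features))
})

test_that("noiseless linear campaign reproduces coefficient times concentration", {
  camp <- tiny_lc_campaign(seed = 1, noise_cv = 0, dispersion = 0)
  tot <- aggregate(intensity ~ sample_id + compound_id,
                   camp$features, sum)
  an <- merge(tot[tot$compound_id == "analyte", ],
              unique(camp$design[, c("sample_id", "compound_id",
                                     "true_conc")]))
  expect_equal(an$intensity, 2e5 * an$true_conc, tolerance = 1e-9)
})

test_that("feature intensities conserve the latent total response", {
  camp <- tiny_lc_campaign(seed = 5, runs = 2, adduct_drift = 20)
  tot <- aggregate(intensity ~ run_id + sample_id + compound_id,
                   camp$features, sum)
  m <- merge(tot, camp$truth$latent_totals,
             by = c("run_id", "sample_id", "compound_id"))
  expect_equal(m$intensity, m$total_response, tolerance = 1e-9)
})

test_that("saturating response curves bend down and overload bends up", {
  sat <- tiny_lc_campaign(seed = 2, noise_cv = 0, dispersion = 0,
                          nonlinearity = "saturating", saturation = 0.5,
                          levels = c(0.1, 1, 10))
  tot <- aggregate(intensity ~ sample_id + compound_id, sat$features, sum)
  an <- merge(tot[tot$compound_id == "analyte", ],
              unique(sat$design[, c("sample_id", "compound_id", "true_conc")]))
  an <- an[order(an$true_conc), ]
  rel <- an$intensity / an$true_conc
  expect_lt(rel[nrow(an)], rel[1])  # response per conc drops at the top

  ov <- tiny_lc_campaign(seed = 2, noise_cv = 0, dispersion = 0,
                         nonlinearity = "overload_enhancing",
                         saturation = 0.5, levels = c(0.1, 1, 10))
  tov <- aggregate(intensity ~ sample_id + compound_id, ov$features, sum)
  anv <- merge(tov[tov$compound_id == "analyte", ],
               unique(ov$design[, c("sample_id", "compound_id", "true_conc")]))
  anv <- anv[order(anv$true_conc), ]
  relv <- anv$intensity / anv$true_conc
  expect_gt(relv[nrow(anv)], relv[1])
})

test_that("infinite drift concentration pins adduct ratios to propensities", {
  camp <- tiny_lc_campaign(seed = 3, runs = 4, adduct_drift = Inf)
  sf <- camp$truth$species_fractions
  an <- sf[sf$compound_id == "analyte", ]
  expect_equal(an$fraction[an$species == "[M+H]+"], rep(0.6, 4))
  expect_equal(an$fraction[an$species == "[M+Na]+"], rep(0.4, 4))
  # finite drift actually moves them
  drift <- tiny_lc_campaign(seed = 3, runs = 4, adduct_drift = 20)
  dan <- drift$truth$species_fractions
  dan <- dan[dan$compound_id == "analyte" & dan$species == "[M+H]+", ]
  expect_gt(sd(dan$fraction), 0)
})

test_that("distinct compound dispersions yield detectably unequal RRF spread", {
  istd <- compound_spec("istd", "C8H15O5P", "LCMS_pos", 1e5,
                        adducts = c("[M+H]+" = 1), dispersion = 0)
  tight <- compound_spec("tight", "C12H20O7", "LCMS_pos", 1e5,
                         adducts = c("[M+H]+" = 1), dispersion = 0.05,
                         istd_id = "istd")
  loose <- compound_spec("loose", "C18H35NO", "LCMS_pos", 1e5,
                         adducts = c("[M+H]+" = 1), dispersion = 0.30,
                         istd_id = "istd")
  camp <- simulate_campaign(list(tight, loose, istd),
                            campaign_config(runs = 50, levels = c(0.1, 0.5, 1),
                                            injections = 2, noise_cv = 0.02,
                                            seed = 99))
  resp <- quantify_features(camp$features, camp$design,
                            models = list(quant_model("ECC")))
  tab <- rrf_table(resp, camp$design, c(0.05, 1),
                   acceptance_criteria("LCMS_pos"))
  a <- tab$rrf[tab$compound_id == "tight" & tab$accepted]
  b <- tab$rrf[tab$compound_id == "loose" & tab$accepted]
  expect_gte(length(a), 40)
  lv <- levene_test(a, b, alpha = 0.05)
  expect_true(lv$significant)
  expect_gt(sd(b) / sd(a), 2)
})

test_that("day-to-day RRF spread converges to the lognormal closed form", {
  sigma <- 0.3
  istd <- compound_spec("istd", "C8H15O5P", "LCMS_pos", 1e5,
                        adducts = c("[M+H]+" = 1), dispersion = 0)
  an <- compound_spec("an", "C12H20O7", "LCMS_pos", 1e5,
                      adducts = c("[M+H]+" = 1), dispersion = sigma,
                      istd_id = "istd")
  camp <- simulate_campaign(list(an, istd),
                            campaign_config(runs = 500, levels = 1,
                                            injections = 1, noise_cv = 0,
                                            seed = 61))
  resp <- quantify_features(camp$features, camp$design,
                            models = list("ECC"))
  d <- merge(resp[resp$compound_id == "an", ], camp$design)
  rrf <- rrf_single_point(d$corrected, d$true_conc,
                          camp$truth$config$istd_conc)
  expect_equal(summarize_population(rrf)$rsd, sqrt(exp(sigma^2) - 1),
               tolerance = 0.10)
})

test_that("an NTE sample shares its run context and recovers truth noiselessly", {
  camp <- tiny_lc_campaign(seed = 4, noise_cv = 0, dispersion = 0)
  nte <- compound_spec("nte", "C12H20O7", "LCMS_pos", 2e5,
                       adducts = c("[M+H]+" = 0.6, "[M+Na]+" = 0.4),
                       dispersion = 0, istd_id = "istd")
  s <- simulate_nte_sample(nte, 0.15, camp, "run001")
  expect_setequal(unique(s$features$compound_id), c("unknown", "istd"))
  expect_equal(s$truth$true_conc, 0.15)
  # identical chemistry at a calibrated level: features match the standard's
  std <- camp$features[camp$features$sample_id == "L04_I01" &
                         camp$features$compound_id == "analyte", ]
  unk <- s$features[s$features$compound_id == "unknown", ]
  expect_equal(sum(unk$intensity) / sum(std$intensity), 0.15 / 0.25,
               tolerance = 1e-9)
  expect_error(simulate_nte_sample(nte, 0.15, camp, "run999"), "not in campaign")
})
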