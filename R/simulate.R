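#' Define a simulated compound
#'
#' A compound specification for the calibration-campaign simulator: identity,
#' elemental formula, technique, intrinsic response coefficient, its ion
#' ensemble (ESI adduct propensities or EI fragmentation profile), response
#' curvature, and day-to-day response-factor dispersion.
#'
#' @param id Compound identifier (string).
#' @param formula Neutral elemental formula (string or `elemental_formula`).
#' @param technique One of `"GCMS"`, `"LCMS_pos"`, `"LCMS_neg"`.
#' @param response_coef Base response coefficient, area per (ug/mL); > 0.
#' @param adducts Named numeric vector of adduct propensities (labels such as
#'   `"[M+H]+"`), summing to 1. Required for the LCMS techniques.
#' @param fragments Data frame with columns `mz` (Da) and `fraction` (of total
#'   ion current), fractions summing to 1. Required for GCMS.
#' @param saturation Per-compound curvature parameter `k` used by the
#'   campaign's nonlinearity model (0 = linear response).
#' @param dispersion Day-to-day lognormal sigma of the compound's run-level
#'   response multiplier; >= 0.
#' @param istd_id Identifier of the internal standard used to correct this
#'   compound, or `NA` if the compound is itself an internal standard.
#' @return A `compound_spec` object.
#' @examples
#' compound_spec("ethanol", "C2H6O", "LCMS_pos", 1e5,
#'               adducts = c("[M+H]+" = 0.7, "[M+Na]+" = 0.3),
#'               istd_id = "istd1")
#' @export
compound_spec <- function(id, formula, technique,
                          response_coef,
                          adducts = NULL, fragments = NULL,
                          saturation = 0, dispersion = 0.15,
                          istd_id = NA_character_) {
  technique <- match.arg(technique, c("GCMS", "LCMS_pos", "LCMS_neg"))
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.numeric(response_coef), response_coef > 0,
            is.numeric(saturation), saturation >= 0,
            is.numeric(dispersion), dispersion >= 0)
  formula <- as_formula(formula)
  if (technique == "GCMS") {
    if (is.null(fragments))
      stop("GCMS compounds need a fragmentation profile", call. = FALSE)
    stopifnot(is.data.frame(fragments),
              all(c("mz", "fraction") %in% names(fragments)))
    if (abs(sum(fragments$fraction) - 1) > 1e-9)
      stop("fragment fractions must sum to 1", call. = FALSE)
    adducts <- NULL
  } else {
    if (is.null(adducts))
      stop("ESI compounds need adduct propensities", call. = FALSE)
    stopifnot(is.numeric(adducts), !is.null(names(adducts)))
    if (abs(sum(adducts) - 1) > 1e-9)
      stop("adduct propensities must sum to 1", call. = FALSE)
    pol <- if (technique == "LCMS_pos") 1L else -1L
    for (lab in names(adducts)) {
      a <- parse_adduct(lab)
      if (sign(a$charge) != pol)
        stop("adduct ", lab, " polarity inconsistent with ", technique,
             call. = FALSE)
    }
    fragments <- NULL
  }
  structure(list(id = id, formula = formula, technique = technique,
                 response_coef = response_coef, adducts = adducts,
                 fragments = fragments, saturation = saturation,
                 dispersion = dispersion, istd_id = istd_id),
            class = "compound_spec")
}

#' Configure a simulated calibration campaign
#'
#' @param runs Number of instrumental calibrations (days); >= 1.
#' @param levels Calibration concentrations, ug/mL, strictly increasing.
#' @param injections Replicate injections per level.
#' @param adduct_drift Dirichlet concentration controlling day-level
#'   resampling of ESI adduct ratios around each compound's propensities.
#'   Larger = tighter; `Inf` = no drift.
#' @param noise_cv Injection-level multiplicative (lognormal) noise CV.
#' @param nonlinearity Response-vs-concentration model: `"linear"` (g(C) = C),
#'   `"saturating"` (g(C) = C / (1 + kC); ESI droplet saturation), or
#'   `"overload_enhancing"` (g(C) = C (1 + kC), enhancement capped; GC column
#'   or detector overload).
#' @param seed Integer RNG seed; the campaign is reproducible given the seed.
#' @param istd_conc Internal-standard spiked concentration, ug/mL; defaults to
#'   the middle calibration level (mid-range spike).
#' @param rho Fraction of run-level variance shared between compounds
#'   (and with the internal standards) through a common run factor, in [0,1].
#' @param isotope_prune Prune threshold for simulated isotope envelopes
#'   (envelopes are renormalized after pruning so species intensities sum to
#'   the compound total).
#' @param overload_cap Cap on the overload enhancement factor `1 + kC`.
#' @return A `campaign_config` object.
#' @export
campaign_config <- function(runs, levels, injections = 3L,
                            adduct_drift = 50, noise_cv = 0.05,
                            nonlinearity = c("linear", "saturating",
                                             "overload_enhancing"),
                            seed = 1L, istd_conc = NULL, rho = 0.7,
                            isotope_prune = 1e-6, overload_cap = 10) {
  nonlinearity <- match.arg(nonlinearity)
  stopifnot(is.numeric(runs), runs >= 1,
            is.numeric(levels), length(levels) >= 1, all(levels > 0),
            !is.unsorted(levels, strictly = TRUE),
            is.numeric(injections), injections >= 1,
            is.numeric(adduct_drift), adduct_drift > 0,
            is.numeric(noise_cv), noise_cv >= 0,
            is.numeric(rho), rho >= 0, rho <= 1,
            is.numeric(isotope_prune), isotope_prune >= 0, isotope_prune <= 1e-3)
  if (is.null(istd_conc)) istd_conc <- levels[ceiling(length(levels) / 2)]
  stopifnot(istd_conc > 0)
  structure(list(runs = as.integer(runs), levels = as.numeric(levels),
                 injections = as.integer(injections),
                 adduct_drift = adduct_drift, noise_cv = noise_cv,
                 nonlinearity = nonlinearity, seed = as.integer(seed),
                 istd_conc = istd_conc, rho = rho,
                 isotope_prune = isotope_prune, overload_cap = overload_cap),
            class = "campaign_config")
}

# concentration-response shape g(C)
response_shape <- function(conc, k, nonlinearity, cap) {
  switch(nonlinearity,
         linear = conc,
         saturating = conc / (1 + k * conc),
         overload_enhancing = conc * pmin(1 + k * conc, cap))
}

# per-compound table of (species, charge, isotope, mz, within-species
# abundance); envelope pruned then renormalized so abundances sum to 1
species_envelope_table <- function(cmp, prune) {
  rows <- list()
  if (cmp$technique == "GCMS") {
    env <- isotopologue_distribution(cmp$formula,
                                     prune_threshold = min(prune, 1e-3))
    ab <- env$abundance / sum(env$abundance)
    for (i in seq_len(nrow(cmp$fragments))) {
      rows[[i]] <- data.frame(
        species = sprintf("frag:%.4f", cmp$fragments$mz[i]),
        charge = 1L,
        isotope = env$shift,
        mz = cmp$fragments$mz[i] + 1.00335483507 * env$shift,
        sp_fraction = cmp$fragments$fraction[i],
        iso_abundance = ab)
    }
  } else {
    for (i in seq_along(cmp$adducts)) {
      lab <- names(cmp$adducts)[i]
      ion <- apply_adduct(cmp$formula, lab)
      env <- isotopologue_distribution(ion$formula,
                                       prune_threshold = min(prune, 1e-3))
      ab <- env$abundance / sum(env$abundance)
      rows[[i]] <- data.frame(
        species = lab,
        charge = ion$charge,
        isotope = env$shift,
        mz = vapply(env$shift, function(s) ion_mz(ion, s), numeric(1)),
        sp_fraction = unname(cmp$adducts[i]),
        iso_abundance = ab)
    }
  }
  do.call(rbind, rows)
}

# Dirichlet draw around propensities; alpha = Inf returns propensities
draw_species_fractions <- function(prop, alpha) {
  if (!is.finite(alpha)) return(prop)
  g <- stats::rgamma(length(prop), shape = alpha * prop, rate = 1)
  if (sum(g) <= 0) return(prop)
  out <- g / sum(g)
  names(out) <- names(prop)
  out
}

#' Simulate a multi-day calibration campaign
#'
#' Generates centroided feature tables for a standards mix analyzed over
#' repeated instrumental calibrations. Each run draws a compound-level
#' response multiplier (lognormal, partially shared across compounds through a
#' common run factor) and, for ESI compounds, day-level adduct ratios
#' (Dirichlet resampling around the propensities). Each injection draws
#' multiplicative noise. The latent total response of a compound in a sample
#' is `response_coef * run_multiplier * g(C) * noise`, distributed over ion
#' species by the (possibly drifted) species fractions and over isotope peaks
#' by the formula's isotopologue envelope. Internal standards are generated in
#' every sample at the fixed spiked concentration.
#'
#' @param compounds List of [compound_spec()] objects, all of one technique.
#'   Compounds named by another compound's `istd_id` act as internal
#'   standards and must be present in the list.
#' @param config A [campaign_config()].
#' @return A `campaign` object: list with
#'   \describe{
#'     \item{features}{Feature table: `run_id`, `sample_id`, `compound_id`,
#'       `species`, `mz`, `charge`, `isotope`, `intensity`, `rt`.}
#'     \item{design}{Calibration design: `run_id`, `sample_id`,
#'       `compound_id`, `true_conc`, `istd_id`, `istd_conc`.}
#'     \item{truth}{Latent draws: per-run compound multipliers, per-run
#'       species fractions, per-sample latent totals, and the config.}
#'   }
#' @export
simulate_campaign <- function(compounds, config) {
  stopifnot(inherits(config, "campaign_config"))
  if (length(compounds) == 0L)
    stop("empty compound list", call. = FALSE)
  for (cmp in compounds)
    if (!inherits(cmp, "compound_spec"))
      stop("compounds must be compound_spec objects", call. = FALSE)
  ids <- vapply(compounds, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate compound ids", call. = FALSE)
  tech <- unique(vapply(compounds, `[[`, character(1), "technique"))
  if (length(tech) != 1L)
    stop("all compounds must share one technique", call. = FALSE)
  istd_ids <- stats::na.omit(vapply(compounds, `[[`, character(1), "istd_id"))
  missing_istd <- setdiff(istd_ids, ids)
  if (length(missing_istd))
    stop("istd_id not among compounds: ",
         paste(missing_istd, collapse = ", "), call. = FALSE)
  names(compounds) <- ids

  set.seed(config$seed)
  envs <- lapply(compounds, species_envelope_table, prune = config$isotope_prune)
  noise_sd <- sqrt(log(1 + config$noise_cv^2))
  is_istd <- is.na(vapply(compounds, `[[`, character(1), "istd_id"))
  rt <- stats::setNames(seq_along(compounds), ids)  # deterministic elution order

  n_samp <- length(config$levels) * config$injections
  samp <- expand.grid(inj = seq_len(config$injections),
                      level = seq_along(config$levels))
  sample_ids <- sprintf("L%02d_I%02d", samp$level, samp$inj)
  sample_conc <- config$levels[samp$level]

  feat <- vector("list", config$runs * length(compounds))
  truth_run <- vector("list", config$runs)
  truth_frac <- vector("list", config$runs)
  truth_tot <- vector("list", config$runs)
  design <- vector("list", config$runs)
  fi <- 0L

  for (r in seq_len(config$runs)) {
    run_id <- sprintf("run%03d", r)
    u <- stats::rnorm(1)
    eps <- stats::rnorm(length(compounds))
    sig <- vapply(compounds, `[[`, numeric(1), "dispersion")
    z <- sig * (sqrt(config$rho) * u + sqrt(1 - config$rho) * eps)
    mult <- exp(z)
    truth_run[[r]] <- data.frame(run_id = run_id, compound_id = ids,
                                 u = u, z = z, multiplier = mult)
    frac_r <- list()
    tot_r <- list()
    for (ci in seq_along(compounds)) {
      cmp <- compounds[[ci]]
      env <- envs[[ci]]
      sp <- unique(env$species)
      base_frac <- vapply(sp, function(s)
        env$sp_fraction[match(s, env$species)], numeric(1))
      if (cmp$technique != "GCMS") {
        frac <- draw_species_fractions(base_frac, config$adduct_drift)
      } else {
        frac <- base_frac  # EI fragment ratios treated as stable
      }
      frac_r[[ci]] <- data.frame(run_id = run_id, compound_id = cmp$id,
                                 species = sp, fraction = unname(frac))
      conc <- if (is_istd[ci]) rep(config$istd_conc, n_samp) else sample_conc
      g <- response_shape(conc, cmp$saturation, config$nonlinearity,
                          config$overload_cap)
      noise <- if (config$noise_cv > 0)
        exp(stats::rnorm(n_samp, 0, noise_sd) - noise_sd^2 / 2)
      else rep(1, n_samp)
      total <- cmp$response_coef * mult[ci] * g * noise
      tot_r[[ci]] <- data.frame(run_id = run_id, sample_id = sample_ids,
                                compound_id = cmp$id, true_conc = conc,
                                total_response = total)
      # intensity[sample, peak] = total[sample] * species fraction * envelope
      peak_w <- frac[env$species] * env$iso_abundance
      inten <- as.vector(outer(peak_w, total))  # peaks vary fastest
      np <- nrow(env)
      fi <- fi + 1L
      feat[[fi]] <- data.frame(
        run_id = run_id,
        sample_id = rep(sample_ids, each = np),
        compound_id = cmp$id,
        species = rep(env$species, n_samp),
        mz = rep(env$mz, n_samp),
        charge = rep(env$charge, n_samp),
        isotope = rep(env$isotope, n_samp),
        intensity = inten,
        rt = unname(rt[cmp$id]))
    }
    truth_frac[[r]] <- do.call(rbind, frac_r)
    truth_tot[[r]] <- do.call(rbind, tot_r)
    design[[r]] <- data.frame(
      run_id = run_id,
      sample_id = rep(sample_ids, times = length(compounds)),
      compound_id = rep(ids, each = n_samp),
      true_conc = unlist(lapply(seq_along(compounds), function(ci)
        if (is_istd[ci]) rep(config$istd_conc, n_samp) else sample_conc)),
      istd_id = rep(vapply(compounds, `[[`, character(1), "istd_id"),
                    each = n_samp),
      istd_conc = rep(ifelse(is_istd, NA_real_, config$istd_conc),
                      each = n_samp))
  }

  structure(list(
    features = do.call(rbind, feat[seq_len(fi)]),
    design = do.call(rbind, design),
    truth = list(config = config,
                 compounds = compounds,
                 run_effects = do.call(rbind, truth_run),
                 species_fractions = do.call(rbind, truth_frac),
                 latent_totals = do.call(rbind, truth_tot))),
    class = "campaign")
}

#' @export
print.campaign <- function(x, ...) {
  cat("<campaign>", length(unique(x$features$run_id)), "runs,",
      nrow(x$features), "features,",
      length(x$truth$compounds), "compounds\n")
  invisible(x)
}

#' Simulate a nontarget-extractable sample inside a campaign run
#'
#' Generates feature rows for an unknown (nontarget extractable, NTE) in one
#' run of an existing simulated campaign, reusing that run's common run factor
#' and internal standards so the sample is quantifiable against the run's
#' calibration. The NTE's features carry `compound_id = "unknown"`.
#'
#' @param nte [compound_spec()] for the unknown compound (its `istd_id` names
#'   the campaign internal standard to spike).
#' @param true_conc True concentration, ug/mL; > 0.
#' @param campaign A `campaign` from [simulate_campaign()].
#' @param run_id Run to attach the sample to.
#' @param sample_id Sample identifier for the new sample.
#' @return List with `features` (NTE + internal-standard rows), `design`
#'   (the internal-standard bookkeeping row), and `truth` (the NTE's true
#'   concentration and latent draws).
#' @export
simulate_nte_sample <- function(nte, true_conc, campaign,
                                run_id, sample_id = "NTE01") {
  stopifnot(inherits(campaign, "campaign"), inherits(nte, "compound_spec"),
            is.numeric(true_conc), true_conc > 0)
  config <- campaign$truth$config
  re <- campaign$truth$run_effects
  re <- re[re$run_id == run_id, , drop = FALSE]
  if (nrow(re) == 0L)
    stop("run ", sQuote(run_id), " not in campaign", call. = FALSE)
  if (is.na(nte$istd_id) || !(nte$istd_id %in% re$compound_id))
    stop("NTE istd_id must name a campaign internal standard", call. = FALSE)

  u <- re$u[1]
  z <- nte$dispersion * (sqrt(config$rho) * u +
                           sqrt(1 - config$rho) * stats::rnorm(1))
  mult <- exp(z)
  noise_sd <- sqrt(log(1 + config$noise_cv^2))
  noise <- function() if (config$noise_cv > 0)
    exp(stats::rnorm(1, 0, noise_sd) - noise_sd^2 / 2) else 1

  one_compound_rows <- function(cmp, cid, conc, mult_c, frac = NULL) {
    env <- species_envelope_table(cmp, config$isotope_prune)
    sp <- unique(env$species)
    if (is.null(frac)) {
      frac <- vapply(sp, function(s)
        env$sp_fraction[match(s, env$species)], numeric(1))
    }
    g <- response_shape(conc, cmp$saturation, config$nonlinearity,
                        config$overload_cap)
    total <- cmp$response_coef * mult_c * g * noise()
    data.frame(run_id = run_id, sample_id = sample_id, compound_id = cid,
               species = env$species, mz = env$mz, charge = env$charge,
               isotope = env$isotope,
               intensity = total * frac[env$species] * env$iso_abundance,
               rt = 0)
  }

  nte_rows <- one_compound_rows(nte, "unknown", true_conc, mult)
  istd_cmp <- campaign$truth$compounds[[nte$istd_id]]
  sf <- campaign$truth$species_fractions
  sf <- sf[sf$run_id == run_id & sf$compound_id == istd_cmp$id, , drop = FALSE]
  istd_frac <- stats::setNames(sf$fraction, sf$species)
  istd_rows <- one_compound_rows(istd_cmp, istd_cmp$id, config$istd_conc,
                                 re$multiplier[match(istd_cmp$id,
                                                     re$compound_id)],
                                 frac = istd_frac)
  list(
    features = rbind(nte_rows, istd_rows),
    design = data.frame(run_id = run_id, sample_id = sample_id,
                        compound_id = istd_cmp$id,
                        true_conc = config$istd_conc,
                        istd_id = NA_character_, istd_conc = NA_real_),
    truth = list(true_conc = true_conc, multiplier = mult, run_u = u,
                 istd_id = istd_cmp$id))
}
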