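# Independent oracles used across the suite. These deliberately avoid the
# package's computation paths: the isotope oracle enumerates multinomial
# isotope assignments, the WLS oracle solves the 2x2 normal equations, and
# the Welch oracle evaluates the textbook formulas.

# all compositions of n into k non-negative parts
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  do.call(rbind, lapply(0:n, function(i) cbind(i, compositions(n - i, k - 1L))))
}

# exact isotopologue distribution by exhaustive multinomial enumeration,
# combined across elements by expanding the cartesian product of shifts
oracle_isotopologues <- function(counts) {
  tab <- isotope_table()
  per_elem <- lapply(names(counts), function(el) {
    rows <- tab[tab$element == el, ]
    cmp <- compositions(counts[[el]], nrow(rows))
    probs <- apply(cmp, 1, function(cc) {
      exp(lfactorial(sum(cc)) - sum(lfactorial(cc))) * prod(rows$abundance^cc)
    })
    shifts <- as.vector(cmp %*% rows$shift)
    list(shift = shifts, prob = probs)
  })
  grid_idx <- expand.grid(lapply(per_elem, function(e) seq_along(e$prob)))
  shift <- rowSums(mapply(function(e, idx) e$shift[idx], per_elem, grid_idx))
  prob <- Reduce(`*`, mapply(function(e, idx) e$prob[idx], per_elem, grid_idx,
                             SIMPLIFY = FALSE))
  agg <- tapply(prob, shift, sum)
  data.frame(shift = as.integer(names(agg)), abundance = as.vector(agg))
}

# closed-form weighted least squares from the normal equations
oracle_wls <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  list(slope = (sw * sxy - sx * sy) / det,
       intercept = (sy * sxx - sx * sxy) / det)
}

# textbook Welch t and Welch-Satterthwaite df
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# small single-analyte campaign used by several tests
tiny_lc_campaign <- function(seed = 1, runs = 1, noise_cv = 0.05,
                             dispersion = 0.15,
                             nonlinearity = "linear", saturation = 0,
                             levels = c(0.025, 0.05, 0.1, 0.25, 0.5, 1),
                             adduct_drift = Inf) {
  istd <- compound_spec("istd", "C8H15O5P", "LCMS_pos", 1e5,
                        adducts = c("[M+H]+" = 1), dispersion = 0)
  an <- compound_spec("analyte", "C12H20O7", "LCMS_pos", 2e5,
                      adducts = c("[M+H]+" = 0.6, "[M+Na]+" = 0.4),
                      saturation = saturation, dispersion = dispersion,
                      istd_id = "istd")
  simulate_campaign(list(an, istd),
                    campaign_config(runs = runs, levels = levels,
                                    injections = 3, noise_cv = noise_cv,
                                    nonlinearity = nonlinearity,
                                    adduct_drift = adduct_drift,
                                    seed = seed))
}
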