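#' Packaged compound fixtures
#'
#' Deterministic [compound_spec()] sets that reproduce the qualitative ion
#' chemistry behind the common quantitation-model biases:
#' \describe{
#'   \item{bht}{EI profile of a hindered phenol that fragments little: a
#'     dominant base peak (fraction 0.55), so single-ion bias is minimal.}
#'   \item{methyl_oleate}{EI profile of a fatty-acid methyl ester with
#'     extensive fragmentation: 40 fragments with intensity of rank i
#'     proportional to i^(-0.7); the base peak carries only
#'     1 / sum(i^(-0.7)) of the ion current, so a base-peak EIC
#'     under-reports by more than four-fold.}
#'   \item{dtdpp}{ESI-positive multi-adduct ester (dilauryl thiodipropionate
#'     C30H58O4S): [M+H]+, [M+NH4]+, [M+Na]+, [M+ACN+NH4]+ with no single
#'     dominant species, so a single-adduct EIC is biased low.}
#'   \item{d8}{Cyclic siloxane C16H48O8Si8 whose eight silicons push the
#'     monoisotopic fraction below one half.}
#'   \item{eicosane, chrysene}{A heavily fragmenting n-alkane (C20H42; 30
#'     fragments, rank^(-0.7)) and a barely fragmenting fused aromatic
#'     (C18H12; base peak fraction 0.8) sharing a deuterated-phthalate-like
#'     internal standard — the surrogate/NTE pair for semiquantitation bias.}
#'   \item{triethyl_citrate, oleamide}{ESI-positive esters/amides with
#'     saturating high-concentration behaviour (curvature k = 0.3) and, for
#'     the pair, distinct day-to-day dispersions (0.15 vs 0.30) — the
#'     unequal-variance demonstration pair.}
#'   \item{dehp}{EI phthalate dominated by the m/z 149 fragment, with
#'     overload-enhancing curvature (k = 0.2) at high on-column loads.}
#'   \item{istd_gc, istd_lc}{Isotopically-labeled-style internal standards
#'     (low day-to-day dispersion) for the GC and LC sets.}
#' }
#'
#' All fixtures share `response_coef = 1e5` so quantitation-model effects are
#' isolated from intrinsic response differences.
#'
#' @return Named list of `compound_spec` objects.
#' @export
packaged_fixtures <- function() {
  rank_profile <- function(n, expo, mz0, step = 14) {
    w <- seq_len(n)^(-expo)
    data.frame(mz = mz0 + step * (seq_len(n) - 1L), fraction = w / sum(w))
  }
  base_peak_profile <- function(bp_frac, n, mz0, step = 14) {
    rest <- rep((1 - bp_frac) / (n - 1L), n - 1L)
    data.frame(mz = mz0 + step * (seq_len(n) - 1L),
               fraction = c(bp_frac, rest))
  }
  list(
    bht = compound_spec(
      "bht", "C15H24O", "GCMS", 1e5,
      fragments = base_peak_profile(0.55, 6, 205.1587),
      dispersion = 0.15, istd_id = "istd_gc"),
    methyl_oleate = compound_spec(
      "methyl_oleate", "C19H36O2", "GCMS", 1e5,
      fragments = rank_profile(40, 0.7, 55.0542),
      dispersion = 0.15, istd_id = "istd_gc"),
    eicosane = compound_spec(
      "eicosane", "C20H42", "GCMS", 1e5,
      fragments = rank_profile(30, 0.7, 57.0699),
      dispersion = 0.15, istd_id = "istd_gc"),
    chrysene = compound_spec(
      "chrysene", "C18H12", "GCMS", 1e5,
      fragments = base_peak_profile(0.8, 4, 228.0934),
      dispersion = 0.15, istd_id = "istd_gc"),
    d8 = compound_spec(
      "d8", "C16H48O8Si8", "GCMS", 1e5,
      fragments = base_peak_profile(0.6, 5, 577.1399),
      dispersion = 0.15, istd_id = "istd_gc"),
    istd_gc = compound_spec(
      "istd_gc", "C8H8O", "GCMS", 1e5,  # acetophenone-like labeled standard
      fragments = base_peak_profile(0.7, 3, 120.0570),
      dispersion = 0.05),
    dtdpp = compound_spec(
      "dtdpp", "C30H58O4S", "LCMS_pos", 1e5,
      adducts = c("[M+H]+" = 0.15, "[M+NH4]+" = 0.35,
                  "[M+Na]+" = 0.30, "[M+ACN+NH4]+" = 0.20),
      dispersion = 0.20, istd_id = "istd_lc"),
    triethyl_citrate = compound_spec(
      "triethyl_citrate", "C12H20O7", "LCMS_pos", 1e5,
      adducts = c("[M+H]+" = 0.5, "[M+NH4]+" = 0.3, "[M+Na]+" = 0.2),
      saturation = 0.3, dispersion = 0.15, istd_id = "istd_lc"),
    oleamide = compound_spec(
      "oleamide", "C18H35NO", "LCMS_pos", 1e5,
      adducts = c("[M+H]+" = 0.7, "[M+Na]+" = 0.3),
      saturation = 0.3, dispersion = 0.30, istd_id = "istd_lc"),
    dehp = compound_spec(
      "dehp", "C24H38O4", "GCMS", 1e5,
      fragments = base_peak_profile(0.7, 8, 149.0233),
      saturation = 0.2, dispersion = 0.15, istd_id = "istd_gc"),
    istd_lc = compound_spec(
      "istd_lc", "C8H15O5P", "LCMS_pos", 1e5,  # labeled phosphonoacetate-like
      adducts = c("[M+H]+" = 0.8, "[M+Na]+" = 0.2),
      dispersion = 0.05)
  )
}
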