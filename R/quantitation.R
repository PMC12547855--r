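#' Define a quantitation model
#'
#' The four common mass-spectrometric quantitation models plus the multi-ion
#' EIC variant:
#' \describe{
#'   \item{TIC}{total ion chromatogram — sum of every feature in the sample.}
#'   \item{BPC}{base peak chromatogram — the single most intense peak.}
#'   \item{EIC_single}{one selected (species, isotope) peak.}
#'   \item{EIC_multi}{the monoisotopic peak of every ion species of the
#'     compound, summed.}
#'   \item{ECC}{extracted compound chromatogram — every ion attributed to the
#'     compound: all adducts, multimers, charge states, and isotopes.}
#' }
#'
#' @param kind One of `"TIC"`, `"BPC"`, `"EIC_single"`, `"EIC_multi"`,
#'   `"ECC"`.
#' @param species For `EIC_single`: the species label (adduct label or
#'   fragment tag) to extract, or a numeric m/z matched at `tol_ppm`. May be
#'   left `NULL` for [quantify_features()], which then pins each compound's
#'   base species; [compute_response()] itself requires a selection.
#' @param isotope For `EIC_single`: isotope index (0 = monoisotopic).
#' @param tol_ppm Mass tolerance (ppm) used when `species` is given as m/z.
#' @return A `quant_model` object.
#' @export
quant_model <- function(kind = c("ECC", "TIC", "BPC", "EIC_single",
                                 "EIC_multi"),
                        species = NULL, isotope = 0L, tol_ppm = 10) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(tol_ppm), tol_ppm > 0)
  structure(list(kind = kind, species = species,
                 isotope = as.integer(isotope), tol_ppm = tol_ppm),
            class = "quant_model")
}

#' @export
format.quant_model <- function(x, ...) {
  if (x$kind == "EIC_single")
    paste0(x$kind, "(", x$species, ",iso", x$isotope, ")")
  else x$kind
}

#' @export
print.quant_model <- function(x, ...) {
  cat("<quant_model>", format(x), "\n"); invisible(x)
}

#' Compute a compound's raw response under a quantitation model
#'
#' @param features Feature-table rows. For TIC pass the whole sample's rows
#'   (the TIC is a per-sample quantity); for the other models pass the rows
#'   attributed to one compound in one sample.
#' @param model A [quant_model()].
#' @return Raw response (area). Empty rows give 0 for the TIC-family models
#'   and an error for the EIC models.
#' @examples
#' f <- data.frame(species = c("[M+H]+", "[M+H]+", "[M+Na]+", "[M+Na]+"),
#'                 mz = c(101, 102, 123, 124), isotope = c(0, 1, 0, 1),
#'                 intensity = c(100, 20, 50, 10))
#' compute_response(f, quant_model("ECC"))        # 180
#' compute_response(f, quant_model("EIC_multi"))  # 150
#' @export
compute_response <- function(features, model) {
  stopifnot(inherits(model, "quant_model"), is.data.frame(features))
  if (nrow(features) == 0L) {
    if (model$kind %in% c("EIC_single", "EIC_multi"))
      stop("no features to extract for ", format(model), call. = FALSE)
    return(structure(0, flagged = "empty feature set"))
  }
  switch(model$kind,
    TIC = ,
    ECC = sum(features$intensity),
    BPC = max(features$intensity),
    EIC_multi = sum(features$intensity[features$isotope == 0L]),
    EIC_single = {
      if (is.null(model$species))
        stop("EIC_single needs a species selection", call. = FALSE)
      if (is.numeric(model$species)) {
        tol <- model$species * model$tol_ppm * 1e-6
        hit <- abs(features$mz - model$species) <= tol &
          features$isotope == model$isotope
      } else {
        hit <- features$species == model$species &
          features$isotope == model$isotope
      }
      if (!any(hit))
        stop("EIC selection ", sQuote(paste0(model$species, "/iso",
                                             model$isotope)),
             " not found in feature set", call. = FALSE)
      sum(features$intensity[hit])
    })
}

#' Internal-standard correction
#'
#' @param raw Analyte raw response (area), >= 0.
#' @param istd_raw Internal-standard raw response (area), > 0.
#' @return Corrected response ratio `raw / istd_raw`.
#' @export
istd_correct <- function(raw, istd_raw) {
  stopifnot(is.numeric(raw), is.numeric(istd_raw))
  if (any(raw < 0)) stop("raw response must be >= 0", call. = FALSE)
  if (any(istd_raw <= 0))
    stop("internal-standard response <= 0: ISTD failure for the run",
         call. = FALSE)
  raw / istd_raw
}

#' Ratio of responses under two quantitation models
#'
#' Quantifies the bias a quantitation model introduces relative to another,
#' e.g. a single-adduct EIC against the full ECC for a multi-adduct compound.
#'
#' @param features Feature rows for one compound in one sample.
#' @param model_a,model_b [quant_model()]s; the ratio is A over B.
#' @return `compute_response(features, model_a) / compute_response(features,
#'   model_b)`; errors when the denominator is zero.
#' @export
model_bias_ratio <- function(features, model_a, model_b) {
  b <- compute_response(features, model_b)
  if (b <= 0) stop("denominator model response is zero", call. = FALSE)
  compute_response(features, model_a) / b
}

# default EIC_single selection for a compound: monoisotopic peak of its most
# intense species (base adduct or base fragment)
base_species_of <- function(features) {
  iso0 <- features[features$isotope == 0L, , drop = FALSE]
  iso0$species[which.max(iso0$intensity)]
}

#' Quantify a feature table under one or more models
#'
#' Applies quantitation models compound-by-compound across a feature table
#' and attaches internal-standard-corrected responses. For `EIC_single`
#' without an explicit selection, each compound's base species (its most
#' intense monoisotopic peak in the sample) is used; internal standards are
#' always quantified on their own base species for the EIC and BPC models,
#' mirroring how an analyst pins one ion per standard, and on their ECC for
#' the TIC model (a per-sample TIC cannot serve as an ISTD response).
#'
#' @param features Campaign feature table (see [simulate_campaign()]).
#' @param design Calibration design table matching `features`.
#' @param models List of [quant_model()]s (or kinds as strings).
#' @return A responses data frame: `run_id`, `sample_id`, `compound_id`,
#'   `model`, `raw`, `istd_id`, `istd_raw`, `corrected`.
#' @export
quantify_features <- function(features, design,
                              models = list(quant_model("ECC"))) {
  models <- lapply(models, function(m)
    if (is.character(m)) quant_model(m) else m)
  key <- unique(design[, c("run_id", "sample_id", "compound_id",
                           "istd_id")])
  out <- vector("list", length(models))
  split_feat <- split(features,
                      list(features$run_id, features$sample_id,
                           features$compound_id), drop = TRUE)
  split_samp <- split(features, list(features$run_id, features$sample_id),
                      drop = TRUE)
  fkey <- function(r, s, c) paste(r, s, c, sep = ".")
  for (mi in seq_along(models)) {
    model <- models[[mi]]
    raw <- numeric(nrow(key))
    istd_raw <- rep(NA_real_, nrow(key))
    for (i in seq_len(nrow(key))) {
      rows <- split_feat[[fkey(key$run_id[i], key$sample_id[i],
                               key$compound_id[i])]]
      if (is.null(rows)) rows <- features[0, ]
      m_use <- model
      if (model$kind == "EIC_single" && is.null(model$species))
        m_use <- quant_model("EIC_single", species = base_species_of(rows),
                             isotope = model$isotope, tol_ppm = model$tol_ppm)
      if (model$kind == "TIC") {
        samp_rows <- split_samp[[paste(key$run_id[i], key$sample_id[i],
                                       sep = ".")]]
        raw[i] <- as.numeric(compute_response(samp_rows, m_use))
      } else {
        raw[i] <- as.numeric(compute_response(rows, m_use))
      }
      if (!is.na(key$istd_id[i])) {
        irows <- split_feat[[fkey(key$run_id[i], key$sample_id[i],
                                  key$istd_id[i])]]
        if (is.null(irows) || nrow(irows) == 0L)
          stop("internal standard ", key$istd_id[i], " missing in ",
               key$run_id[i], "/", key$sample_id[i], call. = FALSE)
        mi_use <- m_use
        if (m_use$kind %in% c("EIC_single", "BPC"))
          mi_use <- quant_model("EIC_single",
                                species = base_species_of(irows),
                                isotope = 0L, tol_ppm = m_use$tol_ppm)
        if (m_use$kind == "TIC") mi_use <- quant_model("ECC")
        istd_raw[i] <- as.numeric(compute_response(irows, mi_use))
      }
    }
    out[[mi]] <- data.frame(key[, c("run_id", "sample_id", "compound_id")],
                            model = format(model), raw = raw,
                            istd_id = key$istd_id, istd_raw = istd_raw,
                            corrected = ifelse(is.na(istd_raw), NA_real_,
                                               raw / istd_raw))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
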