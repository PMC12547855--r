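# column schemas for every table the pipeline reads or writes; numeric
# concentration columns are ug/mL, intensities are areas, mz is Da
TABLE_SCHEMAS <- list(
  features = c(run_id = "character", sample_id = "character",
               compound_id = "character", species = "character",
               mz = "numeric", charge = "integer", isotope = "integer",
               intensity = "numeric", rt = "numeric"),
  calibration_design = c(run_id = "character", sample_id = "character",
                         compound_id = "character", true_conc = "numeric",
                         istd_id = "character", istd_conc = "numeric"),
  responses = c(run_id = "character", sample_id = "character",
                compound_id = "character", model = "character",
                raw = "numeric", istd_id = "character",
                istd_raw = "numeric", corrected = "numeric"),
  rrf_table = c(run_id = "character", compound_id = "character",
                model = "character", method = "character",
                weighting = "character", range_low = "numeric",
                range_high = "numeric", rrf = "numeric",
                r_squared = "numeric", n_levels = "integer",
                injection_rsd_max = "numeric", accepted = "logical",
                rejection_reason = "character"),
  population_summary = c(compound_id = "character", model = "character",
                         n = "integer", mean = "numeric", sd = "numeric",
                         rsd = "numeric", min = "numeric", max = "numeric",
                         p2.5 = "numeric", p16 = "numeric", p50 = "numeric",
                         p84 = "numeric", p97.5 = "numeric"),
  welch_pairs = c(a = "character", b = "character", n_a = "integer",
                  n_b = "integer", rsd_a = "numeric", rsd_b = "numeric",
                  rsd_ratio = "numeric", t = "numeric", df = "numeric",
                  p = "numeric", significant = "logical",
                  levene_F = "numeric", levene_p = "numeric",
                  levene_significant = "logical", p_adjusted = "character"),
  nte_quant = c(nte_id = "character", surrogate_id = "character",
                model = "character", conc = "numeric",
                true_conc = "numeric", bias = "numeric")
)

check_schema <- function(df, schema_name, strict = TRUE) {
  schema <- TABLE_SCHEMAS[[schema_name]]
  missing <- setdiff(names(schema), names(df))
  if (length(missing))
    stop(schema_name, " table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Read a pipeline table from CSV
#'
#' Reads one of the pipeline's typed tables, validating the header against
#' the packaged schema and coercing column types. Rows that fail coercion
#' (e.g. non-numeric intensity) are collected; with `strict = TRUE` any
#' malformed row is an error that names the rows, otherwise they are dropped
#' with a warning carrying the same detail.
#'
#' @param path CSV file path.
#' @param schema One of `names(rrfkit:::TABLE_SCHEMAS)`: `"features"`,
#'   `"calibration_design"`, `"responses"`, `"rrf_table"`,
#'   `"population_summary"`, `"welch_pairs"`, `"nte_quant"`.
#' @param strict Error (rather than warn and drop) on malformed rows.
#' @return Data frame with the schema's column types.
#' @export
read_table <- function(path, schema, strict = TRUE) {
  schema <- match.arg(schema, names(TABLE_SCHEMAS))
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  check_schema(df, schema)
  types <- TABLE_SCHEMAS[[schema]]
  bad <- rep(FALSE, nrow(df))
  for (col in names(types)) {
    if (types[col] == "character") next
    raw <- df[[col]]
    val <- suppressWarnings(switch(types[col],
                                   numeric = as.numeric(raw),
                                   integer = as.integer(raw),
                                   logical = as.logical(raw)))
    bad <- bad | (is.na(val) & !(is.na(raw) | raw %in% c("", "NA")))
    df[[col]] <- val
  }
  if (any(bad)) {
    msg <- paste0(sum(bad), " malformed row(s) in ", path, ": rows ",
                  paste(utils::head(which(bad), 10), collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; dropped", call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  if (schema == "features" && nrow(df)) {
    key <- do.call(paste, c(df[c("run_id", "sample_id", "compound_id",
                                 "species", "isotope")], sep = "|"))
    if (anyDuplicated(key))
      stop("duplicated feature key (run, sample, compound, species, ",
           "isotope): ", key[anyDuplicated(key)], call. = FALSE)
  }
  if (nrow(df) == 0L)
    warning("empty ", schema, " table read from ", path, call. = FALSE)
  df
}

#' Write a pipeline table to CSV
#'
#' @param df Data frame matching the schema.
#' @param path Output CSV path (directories are created).
#' @param schema Schema name, as in [read_table()].
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, schema) {
  schema <- match.arg(schema, names(TABLE_SCHEMAS))
  check_schema(df, schema)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df[, names(TABLE_SCHEMAS[[schema]])], path,
                   row.names = FALSE)
  invisible(path)
}

population_summary_row <- function(summary, compound_id, model) {
  data.frame(compound_id = compound_id, model = model, n = summary$n,
             mean = summary$mean, sd = summary$sd, rsd = summary$rsd,
             min = summary$min, max = summary$max,
             p2.5 = summary$percentiles[["p2.5"]],
             p16 = summary$percentiles[["p16"]],
             p50 = summary$percentiles[["p50"]],
             p84 = summary$percentiles[["p84"]],
             p97.5 = summary$percentiles[["p97.5"]])
}

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown fields are
#' rejected, and each field accepts exactly one unit (concentrations ug/mL,
#' volumes mL, doses ug/day).
#'
#' @param technique `"GCMS"`, `"LCMS_pos"`, or `"LCMS_neg"`.
#' @param models Character vector of quantitation-model kinds to run.
#' @param range Dynamic range `(low, high)` ug/mL for RRF slopes.
#' @param runs,levels,injections,noise_cv,nonlinearity,adduct_drift Campaign
#'   settings (see [campaign_config()]).
#' @param uf_strategy,uf_cap Uncertainty-factor settings (see
#'   [compute_uf()]).
#' @param dbt,devices_extracted,extraction_volume,devices_per_day Threshold
#'   inputs (see [threshold_inputs()]).
#' @param seed Campaign seed.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(technique = "LCMS_pos",
                            models = c("ECC", "EIC_single", "EIC_multi"),
                            range = c(0.025, 1),
                            runs = 20, levels = c(0.025, 0.05, 0.1, 0.25,
                                                  0.5, 1),
                            injections = 3, noise_cv = 0.05,
                            nonlinearity = "linear", adduct_drift = 50,
                            uf_strategy = "rsd_reciprocal", uf_cap = 0.9,
                            dbt = 100, devices_extracted = 1,
                            extraction_volume = 100, devices_per_day = 1,
                            seed = 1L) {
  cfg <- list(technique = match.arg(technique,
                                    c("GCMS", "LCMS_pos", "LCMS_neg")),
              models = models, range = as.numeric(range),
              runs = runs, levels = as.numeric(levels),
              injections = injections, noise_cv = noise_cv,
              nonlinearity = nonlinearity, adduct_drift = adduct_drift,
              uf_strategy = uf_strategy, uf_cap = uf_cap, dbt = dbt,
              devices_extracted = devices_extracted,
              extraction_volume = extraction_volume,
              devices_per_day = devices_per_day, seed = as.integer(seed))
  stopifnot(length(cfg$range) == 2, cfg$range[1] < cfg$range[2],
            all(cfg$models %in% c("TIC", "BPC", "EIC_single", "EIC_multi",
                                  "ECC")))
  structure(cfg, class = "pipeline_config")
}

#' Read and validate a pipeline configuration from JSON
#'
#' @param path JSON file with fields as in [pipeline_config()]; unknown
#'   fields are an error naming the field.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, raw)
}

#' Write the run manifest
#'
#' Records the configuration hash, seed, package version, and every file a
#' pipeline stage wrote — the audit trail that ties outputs to their exact
#' configuration.
#'
#' @param dir Output directory.
#' @param config The `pipeline_config` used.
#' @param files Character vector of output files (relative to `dir`).
#' @param counts Optional named list of record counts per stage.
#' @return Path of the written `manifest.json`, invisibly.
#' @export
write_manifest <- function(dir, config, files, counts = list()) {
  manifest <- list(
    config_hash = digest::digest(unclass(config), algo = "sha256"),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("rrfkit")),
    files = as.list(files),
    record_counts = counts,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
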