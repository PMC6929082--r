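# CSV / JSON interchange.
#
# CSV dialect: UTF-8, '.' decimal separator, header
#   fruit_id,side,subset,temperature_C,diameter_mm,ssc_brix,r_0432.0,...,r_1147.0
# (the generator's extra provenance columns acquisition_index and chl are
# written too when present, immediately after ssc_brix).

#' Write a population tibble to CSV
#'
#' @param samples Population tibble (see [generate_population()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(samples, path) {
  lead <- intersect(
    c("fruit_id", "side", "subset", "temperature_C", "diameter_mm",
      "ssc_brix", "acquisition_index", "chl"),
    names(samples)
  )
  spec_cols <- grep("^r_", names(samples), value = TRUE)
  readr::write_csv(samples[, c(lead, spec_cols)], path)
  invisible(path)
}

#' Read a population CSV back into a tibble
#'
#' @param path CSV path written by [write_population_csv()] (or any file in
#'   the same dialect).
#' @return Population tibble.
#' @export
read_population_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  spec_cols <- grep("^r_", names(out), value = TRUE)
  if (length(spec_cols) == 0) abort("no reflectance columns (r_*) found")
  out$subset <- as.character(out$subset)
  out
}

#' Serialize a run configuration (generator + seed + preprocessing grid) to JSON
#'
#' @param config A [generator_config()].
#' @param path Output JSON path.
#' @param preproc_grid Optional list of [preproc_spec()] objects to record.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path, preproc_grid = NULL) {
  stopifnot(inherits(config, "generator_config"))
  x <- unclass(config)
  x$band_library <- as.data.frame(x$band_library)
  x$temp_regimes <- as.data.frame(x$temp_regimes)
  if (!is.null(preproc_grid)) {
    x$preproc_grid <- lapply(preproc_grid, function(s) unclass(s))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration JSON
#'
#' @param path JSON path written by [write_run_config()].
#' @return A list with elements `config` ([generator_config()]) and
#'   `preproc_grid` (list of [preproc_spec()] or `NULL`).
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- NULL
  if (!is.null(x$preproc_grid)) {
    grid <- lapply(seq_len(nrow(as.data.frame(x$preproc_grid))), function(i) {
      s <- as.data.frame(x$preproc_grid)[i, ]
      preproc_spec(base = s$base, snv = s$snv, augmented = s$augmented,
                   spectral_range = s$spectral_range,
                   sg_window = s$sg_window, sg_polyorder = s$sg_polyorder,
                   trim_points = s$trim_points, chl_cutoff_nm = s$chl_cutoff_nm)
    })
    x$preproc_grid <- NULL
  }
  drift_names <- LETTERS[1:5]
  cfg <- generator_config(
    n_fruits = x$n_fruits, seed = x$seed,
    ssc_mean = x$ssc_mean, ssc_sd = x$ssc_sd,
    ssc_range = unlist(x$ssc_range),
    delta_ssc_sd = x$delta_ssc_sd, ssc_ref_noise_sd = x$ssc_ref_noise_sd,
    size_range_mm = unlist(x$size_range_mm), size_mean_mm = x$size_mean_mm,
    size_sd_mm = x$size_sd_mm,
    temp_regimes = as_tibble(x$temp_regimes),
    temp_range_C = unlist(x$temp_range_C),
    subset_fractions = unlist(x$subset_fractions),
    drift_ssc_offset = setNames(unlist(x$drift_ssc_offset), drift_names),
    drift_baseline_tilt = setNames(unlist(x$drift_baseline_tilt), drift_names),
    drift_size_extremes_E = x$drift_size_extremes_E,
    chl_mean = x$chl_mean, chl_sd = x$chl_sd, chl_ssc_cor = x$chl_ssc_cor,
    band_library = as_tibble(x$band_library),
    baseline_coefs = unlist(x$baseline_coefs),
    noise_sd = x$noise_sd,
    temp_shift_nm_per_degC = x$temp_shift_nm_per_degC,
    temp_broaden_per_degC = x$temp_broaden_per_degC,
    scatter_slope_per_mm = x$scatter_slope_per_mm
  )
  list(config = cfg, preproc_grid = grid)
}
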