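#' Wavelength grid of the simulated spectrometer
#'
#' 1024 points evenly spaced between 432 and 1147 nm, the detector-array grid
#' all simulated spectra live on.
#'
#' @return Numeric vector of length 1024 (nm), strictly increasing.
#' @export
#' @examples
#' head(wavelength_grid())
wavelength_grid <- function() {
  seq(432, 1147, length.out = 1024L)
}

#' Column labels for reflectance features
#' @noRd
reflectance_labels <- function(wl = wavelength_grid()) {
  sprintf("r_%06.1f", wl)
}

#' Default absorption band library
#'
#' Gaussian bands used by the spectral simulator: one chlorophyll band near
#' 680 nm (amplitude per unit of the chlorophyll latent variable), sugar O-H /
#' C-H overtone bands at 755, 840, 920, 970 and 1100 nm (amplitude per degree
#' Brix of SSC), and fixed water-background bands. Amplitudes and widths are
#' calibrated to two properties of the emulated instrument: (i) at the default
#' SSC spread the SSC-driven spectral variance at the band centers is roughly
#' an order of magnitude above the additive noise floor, and (ii) after the
#' support-vector input scaling (see [scale_for_svm()]) all non-SNV spectral
#' features land inside the `[-0.2, 0.2]` interval the real instrument's data
#' occupy.
#'
#' @return A tibble with columns `center_nm`, `width_nm`, `amplitude`, `kind`
#'   (one of `"ssc"`, `"chl"`, `"water"`).
#' @export
default_band_library <- function() {
  tibble(
    center_nm = c(680, 755, 840, 920, 970, 1100, 970, 760, 1135),
    width_nm  = c(50, 30, 22, 26, 33, 24, 100, 38, 60),
    amplitude = c(0.055, 0.0032, 0.0026, 0.0030, 0.0034, 0.0026,
                  0.18, 0.045, 0.08),
    kind      = c("chl", "ssc", "ssc", "ssc", "ssc", "ssc",
                  "water", "water", "water")
  )
}

#' Configuration for the synthetic pear population generator
#'
#' Defines the study conditions the generator emulates: a packinghouse-scale
#' pear survey with two reflectance spectra and two destructive SSC
#' measurements per fruit (opposite equatorial sides), fruit collected in five
#' chronological subsets A-E spanning two harvest seasons, three temperature
#' regimes (chilled, ambient, heated) and a wide size range.
#'
#' Defaults reproduce the published summary statistics of the emulated survey:
#' SSC mean 13 degrees Brix with ~95% of fruit in 9.5-16.4 (sd 1.725) and hard
#' range 7-19.1; equatorial diameter 43-81 mm, mean 60; peel temperature
#' 4.7-39 C; per-fruit side-to-side SSC difference with sd 0.62 degrees Brix.
#'
#' @param n_fruits Number of fruits (two samples each are generated).
#' @param seed Integer seed; the whole population is a pure function of
#'   `(config, seed)`.
#' @param ssc_mean,ssc_sd Mean / sd (degrees Brix) of the per-fruit SSC
#'   truncated normal.
#' @param ssc_range Length-2 numeric, hard truncation range for SSC.
#' @param delta_ssc_sd Sd (degrees Brix) of the side-to-side SSC difference
#'   within one fruit.
#' @param ssc_ref_noise_sd Sd of additional reference-measurement noise added
#'   to the *reported* SSC after the spectrum is simulated (the spectrum
#'   encodes the noise-free value). Default 0; set to a refractometer-scale
#'   value to study the irreducible prediction floor.
#' @param size_range_mm,size_mean_mm,size_sd_mm Diameter truncated normal.
#' @param temp_regimes Data frame / tibble with columns `mean_C`, `sd_C`,
#'   `weight` describing the mixture of temperature regimes.
#' @param temp_range_C Hard truncation range for peel temperature.
#' @param subset_fractions Five non-negative weights (sum 1) giving the share
#'   of fruits in chronological subsets A-E.
#' @param drift_ssc_offset Named (A-E) additive SSC offsets emulating the
#'   harvest-season effect (defaults: +0.3 Brix for D and E).
#' @param drift_baseline_tilt Named (A-E) linear absorbance-baseline tilt
#'   coefficients (dimensionless, applied across the grid).
#' @param drift_size_extremes_E If `TRUE`, the second half of subset E
#'   oversamples extreme diameters (big and small fruit).
#' @param chl_mean,chl_sd Mean / sd of the chlorophyll latent variable
#'   (arbitrary units, truncated below at 0.05).
#' @param chl_ssc_cor Correlation between the chlorophyll latent variable and
#'   fruit SSC (ripeness proxy; negative = riper fruit have less peel Chl).
#' @param band_library Band tibble, see [default_band_library()].
#' @param baseline_coefs Length-3 numeric `(b0, b1, b2)` of the smooth
#'   absorbance baseline `b0 + b1*u + b2*u^2`, `u` = scaled wavelength in
#'   `[0, 1]`.
#' @param noise_sd Additive spectral noise sd, absorbance units.
#' @param baseline_jitter_sd Sd of the per-sample random smooth-baseline
#'   coefficients (absorbance units): each sample gets its own small random
#'   quadratic baseline perturbation, emulating the variable fiber-to-fruit
#'   distance and lighting of a non-contact setup.
#' @param temp_shift_nm_per_degC Band-center shift per degree C away from 20 C.
#' @param temp_broaden_per_degC Relative band-width change per degree C above
#'   20 C (monotone: warmer fruit have broader, flatter bands; broadening is
#'   area-conserving so peak heights scale with its inverse).
#' @param scatter_slope_per_mm Size-dependent multiplicative reflectance
#'   scatter slope per mm of diameter away from 60 mm.
#'
#' @return An object of class `generator_config` (a validated list).
#' @export
#' @examples
#' cfg <- generator_config(n_fruits = 50, seed = 1)
#' cfg$ssc_mean
generator_config <- function(n_fruits = 1650L,
                             seed = 1L,
                             ssc_mean = 13,
                             ssc_sd = 1.725,
                             ssc_range = c(7, 19.1),
                             delta_ssc_sd = 0.62,
                             ssc_ref_noise_sd = 0,
                             size_range_mm = c(43, 81),
                             size_mean_mm = 60,
                             size_sd_mm = 7,
                             temp_regimes = tibble(
                               mean_C = c(6, 22, 35),
                               sd_C = c(2, 3, 2.5),
                               weight = c(0.25, 0.5, 0.25)
                             ),
                             temp_range_C = c(4.7, 39),
                             subset_fractions = rep(0.2, 5),
                             drift_ssc_offset = c(A = 0, B = 0, C = 0,
                                                  D = 0.3, E = 0.3),
                             drift_baseline_tilt = c(A = 0, B = 0, C = 0,
                                                     D = 0.02, E = 0.02),
                             drift_size_extremes_E = TRUE,
                             chl_mean = 1,
                             chl_sd = 0.35,
                             chl_ssc_cor = -0.6,
                             band_library = default_band_library(),
                             baseline_coefs = c(0.40, -0.10, 0.05),
                             noise_sd = 0.0015,
                             baseline_jitter_sd = 0.01,
                             temp_shift_nm_per_degC = 0.2,
                             temp_broaden_per_degC = 0.005,
                             scatter_slope_per_mm = 0.004) {
  cfg <- list(
    n_fruits = as.integer(n_fruits), seed = as.integer(seed),
    ssc_mean = ssc_mean, ssc_sd = ssc_sd, ssc_range = ssc_range,
    delta_ssc_sd = delta_ssc_sd, ssc_ref_noise_sd = ssc_ref_noise_sd,
    size_range_mm = size_range_mm, size_mean_mm = size_mean_mm,
    size_sd_mm = size_sd_mm,
    temp_regimes = as_tibble(temp_regimes), temp_range_C = temp_range_C,
    subset_fractions = subset_fractions,
    drift_ssc_offset = drift_ssc_offset,
    drift_baseline_tilt = drift_baseline_tilt,
    drift_size_extremes_E = isTRUE(drift_size_extremes_E),
    chl_mean = chl_mean, chl_sd = chl_sd, chl_ssc_cor = chl_ssc_cor,
    band_library = as_tibble(band_library),
    baseline_coefs = baseline_coefs,
    noise_sd = noise_sd,
    baseline_jitter_sd = baseline_jitter_sd,
    temp_shift_nm_per_degC = temp_shift_nm_per_degC,
    temp_broaden_per_degC = temp_broaden_per_degC,
    scatter_slope_per_mm = scatter_slope_per_mm
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

#' @noRd
validate_generator_config <- function(cfg) {
  if (!is.integer(cfg$n_fruits) || cfg$n_fruits < 1L) {
    abort("`n_fruits` must be a positive integer")
  }
  check_number(cfg$ssc_mean, "ssc_mean")
  check_number(cfg$ssc_sd, "ssc_sd", min = 0)
  check_number(cfg$delta_ssc_sd, "delta_ssc_sd", min = 0)
  check_number(cfg$ssc_ref_noise_sd, "ssc_ref_noise_sd", min = 0)
  check_number(cfg$noise_sd, "noise_sd", min = 0)
  check_number(cfg$baseline_jitter_sd, "baseline_jitter_sd", min = 0)
  if (length(cfg$ssc_range) != 2L || diff(cfg$ssc_range) <= 0) {
    abort("`ssc_range` must be an increasing length-2 numeric")
  }
  if (cfg$ssc_range[1] > cfg$ssc_mean - 2 * cfg$ssc_sd ||
      cfg$ssc_range[2] < cfg$ssc_mean + 2 * cfg$ssc_sd) {
    abort("`ssc_range` must bracket ssc_mean +/- 2*ssc_sd")
  }
  if (length(cfg$subset_fractions) != 5L ||
      any(cfg$subset_fractions < 0) ||
      abs(sum(cfg$subset_fractions) - 1) > 1e-8) {
    abort("`subset_fractions` must be 5 non-negative weights summing to 1")
  }
  if (any(cfg$temp_regimes$sd_C < 0) || any(cfg$temp_regimes$weight < 0)) {
    abort("temperature regime sds and weights must be non-negative")
  }
  bl <- cfg$band_library
  if (!all(c("center_nm", "width_nm", "amplitude", "kind") %in% names(bl))) {
    abort("`band_library` needs columns center_nm, width_nm, amplitude, kind")
  }
  if (any(bl$center_nm < 432 | bl$center_nm > 1147)) {
    abort("band centers must lie within the 432-1147 nm grid")
  }
  if (abs(cfg$chl_ssc_cor) > 1) abort("`chl_ssc_cor` must be in [-1, 1]")
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  fruits: %d (%d samples), seed %d\n",
              x$n_fruits, 2L * x$n_fruits, x$seed))
  cat(sprintf("  SSC: mean %.2f sd %.3f range [%.1f, %.1f] Brix; dSSC sd %.2f\n",
              x$ssc_mean, x$ssc_sd, x$ssc_range[1], x$ssc_range[2],
              x$delta_ssc_sd))
  cat(sprintf("  size: %.0f-%.0f mm (mean %.0f); temp %.1f-%.0f C, %d regimes\n",
              x$size_range_mm[1], x$size_range_mm[2], x$size_mean_mm,
              x$temp_range_C[1], x$temp_range_C[2], nrow(x$temp_regimes)))
  cat(sprintf("  bands: %d (%d SSC, %d water, %d Chl); noise sd %.4f AU\n",
              nrow(x$band_library), sum(x$band_library$kind == "ssc"),
              sum(x$band_library$kind == "water"),
              sum(x$band_library$kind == "chl"), x$noise_sd))
  invisible(x)
}
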