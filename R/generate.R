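# Synthetic pear population generator.
#
# One fruit yields two samples (opposite equatorial sides) that share
# temperature, diameter and chlorophyll but carry side-specific SSC values and
# independent spectral noise. Spectra are built from a Beer-Lambert-style
# Gaussian band model on the fixed 432-1147 nm grid.

#' Deterministic absorbance band model (no noise)
#'
#' @param ssc,chl,temperature,diameter scalars (recycled to vectors internally
#'   by [simulate_reflectance_matrix()]).
#' @param tilt baseline tilt coefficient for the sample's subset.
#' @param config a [generator_config()].
#' @return absorbance vector on [wavelength_grid()].
#' @noRd
band_absorbance <- function(ssc, chl, temperature, tilt, config,
                            wl = wavelength_grid()) {
  u <- (wl - 432) / 715
  b <- config$baseline_coefs
  A <- b[1] + b[2] * u + b[3] * u^2 + tilt * (u - 0.5)
  dT <- temperature - 20
  for (i in seq_len(nrow(config$band_library))) {
    bd <- config$band_library[i, ]
    ctr <- bd$center_nm + config$temp_shift_nm_per_degC * dT
    broaden <- max(1 + config$temp_broaden_per_degC * dT, 0.2)
    wdt <- bd$width_nm * broaden
    # monotone, area-conserving broadening: warm fruit have broader bands and
    # the integrated absorption does not change, so peak height ~ 1/broaden
    g <- exp(-0.5 * ((wl - ctr) / wdt)^2) / broaden
    amp <- switch(bd$kind,
                  ssc   = bd$amplitude * ssc,
                  chl   = bd$amplitude * chl,
                  water = bd$amplitude,
                  abort(sprintf("unknown band kind '%s'", bd$kind)))
    A <- A + amp * g
  }
  A
}

#' Simulate one reflectance spectrum
#'
#' Builds a synthetic absorbance A(lambda) = smooth baseline + chlorophyll band
#' near 680 nm + SSC-weighted sugar overtone bands + fixed water background,
#' with band centers shifted by `temp_shift_nm_per_degC * (T - 20)` and widths
#' broadened monotonically with `T - 20` (area-conserving, so peak heights
#' drop as bands broaden); converts to reflectance 10^(-A),
#' applies the size-dependent multiplicative scatter factor
#' `1 + scatter_slope_per_mm * (diameter - 60)` and additive absorbance-domain
#' noise, then clips to (0, 1].
#'
#' @param ssc SSC driving the sugar bands (degrees Brix).
#' @param chl Chlorophyll latent variable (arbitrary units).
#' @param temperature Peel temperature (C).
#' @param diameter Equatorial diameter (mm).
#' @param config A [generator_config()].
#' @param tilt Baseline tilt (chronological-drift term), default 0.
#' @param noise If `FALSE`, the deterministic band model is returned exactly
#'   (no additive noise and no per-sample baseline jitter).
#' @return Reflectance vector of length 1024, values in (0, 1].
#' @export
#' @examples
#' cfg <- generator_config(n_fruits = 10)
#' r <- simulate_reflectance(13, 1, 20, 60, cfg, noise = FALSE)
#' range(r)
simulate_reflectance <- function(ssc, chl, temperature, diameter, config,
                                 tilt = 0, noise = TRUE) {
  A <- band_absorbance(ssc, chl, temperature, tilt, config)
  if (noise) {
    if (config$baseline_jitter_sd > 0) {
      u <- (wavelength_grid() - 432) / 715
      jc <- rnorm(3, 0, config$baseline_jitter_sd)
      A <- A + jc[1] + jc[2] * u + jc[3] * u^2
    }
    if (config$noise_sd > 0) A <- A + rnorm(length(A), 0, config$noise_sd)
  }
  r <- 10^(-A) * (1 + config$scatter_slope_per_mm * (diameter - config$size_mean_mm))
  pmin(pmax(r, .Machine$double.eps), 1)
}

#' Vectorised spectral simulation for a whole population
#' @param df tibble with columns ssc, chl, temperature, diameter, tilt
#' @return n x 1024 reflectance matrix
#' @noRd
simulate_reflectance_matrix <- function(df, config) {
  wl <- wavelength_grid()
  n <- nrow(df)
  u <- (wl - 432) / 715
  b <- config$baseline_coefs
  base_row <- b[1] + b[2] * u + b[3] * u^2
  A <- matrix(base_row, n, 1024L, byrow = TRUE) +
    outer(df$tilt, u - 0.5)
  dT <- df$temperature - 20
  ctr_shift <- config$temp_shift_nm_per_degC * dT
  wfac <- pmax(1 + config$temp_broaden_per_degC * dT, 0.2)
  for (i in seq_len(nrow(config$band_library))) {
    bd <- config$band_library[i, ]
    amp <- switch(bd$kind,
                  ssc   = bd$amplitude * df$ssc,
                  chl   = bd$amplitude * df$chl,
                  water = rep(bd$amplitude, n))
    # per-sample shifted center / area-conserving broadened width
    z <- (matrix(wl, n, 1024L, byrow = TRUE) - (bd$center_nm + ctr_shift)) /
      (bd$width_nm * wfac)
    A <- A + (amp / wfac) * exp(-0.5 * z^2)
  }
  if (config$baseline_jitter_sd > 0) {
    jc <- matrix(rnorm(3L * n, 0, config$baseline_jitter_sd), n, 3L)
    A <- A + jc[, 1] + outer(jc[, 2], u) + outer(jc[, 3], u^2)
  }
  if (config$noise_sd > 0) {
    A <- A + matrix(rnorm(n * 1024L, 0, config$noise_sd), n, 1024L)
  }
  r <- 10^(-A) *
    (1 + config$scatter_slope_per_mm * (df$diameter - config$size_mean_mm))
  r[r <= 0] <- .Machine$double.eps
  r[r > 1] <- 1
  r
}

#' Generate a synthetic pear population
#'
#' Draws `n_fruits` fruits and returns a tibble with two rows per fruit (one
#' per equatorial side). Per-fruit mean SSC comes from a truncated normal;
#' side SSC values are `fruit SSC +/- d/2` with `d ~ N(0, delta_ssc_sd)`, so
#' the side-to-side difference has exactly the configured spread. Temperature
#' follows the regime mixture, diameter a truncated normal, and chlorophyll a
#' latent variable anticorrelated with SSC. Fruits are ordered chronologically
#' and assigned to subsets A-E by cumulative `subset_fractions`; subsets D-E
#' receive the configured SSC offset and baseline tilt (harvest-season drift),
#' and the second half of subset E oversamples extreme diameters.
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per sample: `fruit_id`, `side` (0/1),
#'   `subset` (A-E), `acquisition_index`, `temperature_C`, `diameter_mm`,
#'   `chl`, `ssc_brix`, and 1024 reflectance columns `r_0432.0` ...
#'   `r_1147.0`.
#' @export
#' @examples
#' pop <- generate_population(generator_config(n_fruits = 20, seed = 7))
#' dim(pop)
generate_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  n <- config$n_fruits
  with_seed(config$seed, {
    # fruit-level covariates -------------------------------------------------
    z_ssc <- rnorm(n)
    # truncated-normal SSC via inverse CDF but reusing z through its quantile
    p_lo <- stats::pnorm(config$ssc_range[1], config$ssc_mean, config$ssc_sd)
    p_hi <- stats::pnorm(config$ssc_range[2], config$ssc_mean, config$ssc_sd)
    ssc_fruit <- stats::qnorm(p_lo + (p_hi - p_lo) * stats::pnorm(z_ssc),
                              config$ssc_mean, config$ssc_sd)
    rho <- config$chl_ssc_cor
    chl <- config$chl_mean +
      config$chl_sd * (rho * z_ssc + sqrt(1 - rho^2) * rnorm(n))
    chl <- pmax(chl, 0.05)
    diameter <- rtruncnorm(n, config$size_mean_mm, config$size_sd_mm,
                           config$size_range_mm[1], config$size_range_mm[2])
    reg <- sample.int(nrow(config$temp_regimes), n, replace = TRUE,
                      prob = config$temp_regimes$weight)
    temperature <- rtruncnorm(n, config$temp_regimes$mean_C[reg],
                              config$temp_regimes$sd_C[reg],
                              config$temp_range_C[1], config$temp_range_C[2])

    # chronological subsets + drift ------------------------------------------
    cum <- cumsum(config$subset_fractions)
    breaks <- c(0, round(cum[-5] * n), n)
    subset <- rep(LETTERS[1:5], times = diff(breaks))
    # harvest-season drift: the season changes the fruit-matrix-to-refractometer
    # mapping, so the offset lands on the *reported* SSC (after the spectra are
    # simulated), not on the sugar signal driving the bands
    ssc_offset <- unname(config$drift_ssc_offset[subset])
    tilt <- unname(config$drift_baseline_tilt[subset])
    if (config$drift_size_extremes_E) {
      e_idx <- which(subset == "E")
      late_e <- e_idx[e_idx > min(e_idx) + floor(length(e_idx) / 2) - 1L]
      if (length(late_e) > 0) {
        lo <- config$size_range_mm[1]
        hi <- config$size_range_mm[2]
        pick_small <- runif(length(late_e)) < 0.5
        diameter[late_e] <- ifelse(
          pick_small,
          rtruncnorm(length(late_e), lo + 4, 3, lo, config$size_mean_mm),
          rtruncnorm(length(late_e), hi - 4, 3, config$size_mean_mm, hi)
        )
      }
    }

    # side-level values -------------------------------------------------------
    d <- rnorm(n, 0, config$delta_ssc_sd)
    samples <- tibble(
      fruit_id = rep(seq_len(n), each = 2L),
      side = rep(c(0L, 1L), times = n),
      subset = rep(subset, each = 2L),
      acquisition_index = seq_len(2L * n),
      temperature = rep(temperature, each = 2L),
      diameter = rep(diameter, each = 2L),
      chl = rep(chl, each = 2L),
      tilt = rep(tilt, each = 2L),
      ssc = rep(ssc_fruit, each = 2L) +
        rep(d / 2, each = 2L) * rep(c(1, -1), times = n)
    )
    refl <- simulate_reflectance_matrix(samples, config)
    ssc_obs <- samples$ssc + rep(ssc_offset, each = 2L)
    if (config$ssc_ref_noise_sd > 0) {
      ssc_obs <- ssc_obs + rnorm(length(ssc_obs), 0, config$ssc_ref_noise_sd)
    }
    colnames(refl) <- reflectance_labels()
    out <- dplyr::bind_cols(
      tibble(
        fruit_id = samples$fruit_id,
        side = samples$side,
        subset = samples$subset,
        acquisition_index = samples$acquisition_index,
        temperature_C = samples$temperature,
        diameter_mm = samples$diameter,
        chl = samples$chl,
        ssc_brix = ssc_obs
      ),
      as_tibble(refl)
    )
    out
  })
}

#' Remove small fruit from a population
#'
#' Drops both sides of every fruit whose equatorial diameter is below
#' `min_diameter` (specular-contamination filter), preserving row order.
#'
#' @param samples Population tibble from [generate_population()] (or the same
#'   shape read back from CSV).
#' @param min_diameter Minimum diameter in mm (default 42).
#' @return Filtered tibble.
#' @export
#' @examples
#' pop <- generate_population(generator_config(n_fruits = 20, seed = 1))
#' nrow(apply_small_fruit_filter(pop, min_diameter = 55)) <= nrow(pop)
apply_small_fruit_filter <- function(samples, min_diameter = 42) {
  stopifnot(nrow(samples) > 0, "diameter_mm" %in% names(samples))
  dplyr::filter(samples, .data$diameter_mm >= min_diameter)
}

#' Dark/reference reflectance arithmetic
#'
#' Utility mirroring the acquisition convention: the reflectance spectrum is
#' the dark-corrected raw spectrum divided by the dark-corrected white
#' reference, `R = (raw - dark) / (reference - dark)`.
#'
#' @param raw,dark,reference Equal-length numeric vectors of detector counts.
#' @return Reflectance vector.
#' @export
compute_reflectance <- function(raw, dark, reference) {
  stopifnot(length(raw) == length(dark), length(raw) == length(reference))
  denom <- reference - dark
  if (any(denom <= 0)) abort("reference counts must exceed dark counts")
  (raw - dark) / denom
}
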