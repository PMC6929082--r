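# Synthetic-data generator: distributions, band model, filter, determinism.

test_that("population reproduces the configured SSC structure", {
  pop <- tiny_population(n_fruits = 1650, seed = 11)
  expect_equal(nrow(pop), 3300)

  fruit_ssc <- tapply(pop$ssc_brix, pop$fruit_id, mean)
  # drift adds +0.3 to subsets D-E (2/5 of fruits): expected mean 13 + 0.12
  expect_lt(abs(mean(fruit_ssc) - 13.12), 0.1)
  expect_true(all(pop$ssc_brix > 6), "SSC stays near the configured range")

  # ~95% within mean +/- 2 sd (binomial tolerance, drift-free subsets only)
  abc <- pop[pop$subset %in% c("A", "B", "C") & pop$side == 0, ]
  frac <- mean(abs(abc$ssc_brix - 13) <= 2 * 1.725)
  expect_gt(frac, 0.92)
  expect_lt(frac, 0.985)

  # side-to-side difference has the configured spread
  d <- pop$ssc_brix[pop$side == 0] - pop$ssc_brix[pop$side == 1]
  expect_equal(sd(d), 0.62, tolerance = 0.05)
  expect_equal(mean(d), 0, tolerance = 0.05)

  # covariate ranges
  expect_true(all(pop$diameter_mm >= 43 & pop$diameter_mm <= 81))
  expect_true(all(pop$temperature_C >= 4.7 & pop$temperature_C <= 39))
  expect_true(all(pop[, grep("^r_", names(pop))] > 0))
  expect_true(all(pop[, grep("^r_", names(pop))] <= 1))
})

test_that("subset labels partition chronologically with configured shares", {
  pop <- tiny_population(n_fruits = 500, seed = 3)
  counts <- table(pop$subset)
  expect_equal(sort(names(counts)), LETTERS[1:5])
  expect_true(all(abs(counts - 200) <= 2)) # rounding tolerance
  # chronological blocks: acquisition index ranges must not interleave
  rng <- tapply(pop$acquisition_index, pop$subset, range)
  for (i in 1:4) expect_lt(rng[[i]][2], rng[[i + 1]][1])
})

test_that("zero side-variance makes both sides identical and same seed is bit-identical", {
  cfg <- generator_config(n_fruits = 30, seed = 9, delta_ssc_sd = 0)
  pop <- generate_population(cfg)
  expect_equal(pop$ssc_brix[pop$side == 0], pop$ssc_brix[pop$side == 1])

  cfg2 <- generator_config(n_fruits = 30, seed = 9, delta_ssc_sd = 0)
  expect_identical(generate_population(cfg2), pop)

  cfg3 <- generator_config(n_fruits = 30, seed = 10, delta_ssc_sd = 0)
  expect_false(identical(generate_population(cfg3), pop))
})

test_that("noiseless reflectance equals the band-sum model exactly", {
  cfg <- clean_config()
  r <- simulate_reflectance(13, 1, 20, 60, cfg, noise = FALSE)
  # independent re-evaluation of the band-sum formula
  wl <- wavelength_grid()
  u <- (wl - 432) / 715
  b <- cfg$baseline_coefs
  A <- b[1] + b[2] * u + b[3] * u^2
  for (i in seq_len(nrow(cfg$band_library))) {
    bd <- cfg$band_library[i, ]
    amp <- switch(bd$kind, ssc = bd$amplitude * 13, chl = bd$amplitude * 1,
                  water = bd$amplitude)
    A <- A + amp * exp(-0.5 * ((wl - bd$center_nm) / bd$width_nm)^2)
  }
  expect_equal(r, pmin(10^(-A), 1), tolerance = 1e-12)
})

test_that("absorbance differences localize at the driving band", {
  cfg <- clean_config()
  a_of <- function(ssc, chl) {
    -log10(simulate_reflectance(ssc, chl, 20, 60, cfg, noise = FALSE))
  }
  wl <- wavelength_grid()

  # SSC difference concentrated at sugar bands, zero off-band
  d_ssc <- a_of(16, 1) - a_of(10, 1)
  sugar <- cfg$band_library[cfg$band_library$kind == "ssc", ]
  on_band <- wl >= min(sugar$center_nm) - 3 * max(sugar$width_nm) &
    wl <= max(sugar$center_nm) + 3 * max(sugar$width_nm)
  expect_gt(max(abs(d_ssc[on_band])), 0.01)
  expect_lt(max(abs(d_ssc[wl < 600])), 1e-6)

  # chlorophyll difference only near 680 nm (within a few band widths)
  d_chl <- a_of(13, 1.5) - a_of(13, 0)
  chl_w <- cfg$band_library$width_nm[cfg$band_library$kind == "chl"]
  expect_gt(max(abs(d_chl[abs(wl - 680) < chl_w])), 0.05)
  expect_lt(max(abs(d_chl[abs(wl - 680) > 4 * chl_w])), 1e-4)
})

test_that("noiseless absorbance at a band center is linear in SSC with the configured slope", {
  cfg <- clean_config()
  wl <- wavelength_grid()
  band <- cfg$band_library[cfg$band_library$kind == "ssc", ][3, ] # 920 nm
  j <- which.min(abs(wl - band$center_nm))  # nearest grid point to the center
  ssc_vals <- c(8, 10, 12, 14, 16, 18)
  a_j <- vapply(ssc_vals, function(s) {
    -log10(simulate_reflectance(s, 1, 20, 60, cfg, noise = FALSE))[j]
  }, 0)
  slope <- coef(lm(a_j ~ ssc_vals))[[2]]
  # absorbance is linear in SSC with slope = sum over SSC bands of
  # amplitude_k * gaussian_k evaluated at the grid point (neighbouring band
  # shoulders contribute)
  sugar <- cfg$band_library[cfg$band_library$kind == "ssc", ]
  gexp <- sum(sugar$amplitude *
                exp(-0.5 * ((wl[j] - sugar$center_nm) / sugar$width_nm)^2))
  expect_equal(slope, gexp, tolerance = 1e-10)
})

test_that("small-fruit filter removes both sides and preserves order", {
  pop <- tiny_population(n_fruits = 30, seed = 2)
  # force three known diameters onto three fruits
  pop$diameter_mm[pop$fruit_id == 1] <- 40
  pop$diameter_mm[pop$fruit_id == 2] <- 42
  pop$diameter_mm[pop$fruit_id == 3] <- 60
  out <- apply_small_fruit_filter(pop)
  expect_false(any(out$fruit_id == 1))
  expect_equal(sum(out$fruit_id %in% c(2, 3)), 4)
  expect_equal(nrow(out), nrow(pop) - 2)
  expect_true(!is.unsorted(out$acquisition_index))
  # all diameters large -> identity
  expect_identical(apply_small_fruit_filter(pop, min_diameter = 0), pop)
})

test_that("reference-noise field perturbs reported SSC but not the spectrum", {
  base <- clean_config(n_fruits = 50, seed = 77)
  noisy <- clean_config(n_fruits = 50, seed = 77, ssc_ref_noise_sd = 0.62)
  p0 <- generate_population(base)
  p1 <- generate_population(noisy)
  spec_cols <- grep("^r_", names(p0))
  expect_identical(p0[, spec_cols], p1[, spec_cols])
  resid <- p1$ssc_brix - p0$ssc_brix
  expect_gt(sd(resid), 0.4)
  expect_lt(sd(resid), 0.9)
})

test_that("population CSV and run-config JSON round-trip", {
  pop <- tiny_population(n_fruits = 8, seed = 4)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_population_csv(pop, csv)
  back <- read_population_csv(csv)
  expect_equal(back$ssc_brix, pop$ssc_brix, tolerance = 1e-12)
  expect_equal(names(back)[1:6],
               c("fruit_id", "side", "subset", "temperature_C",
                 "diameter_mm", "ssc_brix"))
  expect_equal(grep("^r_", names(back), value = TRUE)[1], "r_0432.0")

  js <- withr::local_tempfile(fileext = ".json")
  cfg <- generator_config(n_fruits = 8, seed = 4, noise_sd = 0.001)
  write_run_config(cfg, js, preproc_grid = list(preproc_spec("deriv1", snv = TRUE)))
  rt <- read_run_config(js)
  expect_identical(generate_population(rt$config), generate_population(cfg))
  expect_equal(data_type_name(rt$preproc_grid[[1]]), "abs1d_snv")
})
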