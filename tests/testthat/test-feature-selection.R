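# Wrapper wavelength selection: ranking, oracle equivalence, mask application.

test_that("rank_features puts the informative column last and breaks ties by index", {
  set.seed(7)
  X <- matrix(rnorm(80 * 6), 80, 6)
  y <- 5 * X[, 4] + rnorm(80, 0, 0.01)
  r <- rank_features(X, y, n_lv = 2)
  expect_equal(r[length(r)], 4)

  # duplicated columns -> bit-identical coefficients -> adjacent ranks,
  # lower index first
  Xd <- cbind(X[, 1], X[, 1], X[, 4])
  rd <- rank_features(Xd, y, n_lv = 1)
  expect_equal(rd, c(1, 2, 3))

  # rank-1 PLS ranking equals |covariance-with-y| ranking (closed form:
  # the 1-LV coefficient is proportional to cov(x_j, y))
  r1 <- rank_features(X, y, n_lv = 1)
  covs <- abs(vapply(seq_len(6), function(j) cov(X[, j], y), 0))
  expect_equal(r1, order(covs))
})

test_that("augmented columns are never ranked or eliminated", {
  set.seed(11)
  X <- matrix(rnorm(60 * 7), 60, 7)
  y <- X[, 2] + 0.5 * X[, 7] + rnorm(60, 0, 0.05)
  is_sp <- c(rep(TRUE, 5), FALSE, FALSE)
  r <- rank_features(X, y, 2, is_spectral = is_sp)
  expect_false(any(r %in% c(6, 7)))
  fsr <- wrapper_select(X, y, max_lv = 2, cv_seed = 3, is_spectral = is_sp)
  expect_length(fsr$retained_mask, 5)
  expect_gte(sum(fsr$retained_mask), fsr$n_lv)
})

test_that("wrapper_select equals a brute-force oracle on a 12-feature instance", {
  set.seed(123)
  n <- 60; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("f%02d", seq_len(p))
  y <- 2 * X[, 3] - 1.5 * X[, 8] + rnorm(n, 0, 0.3)
  max_lv <- 3
  cv_seed <- 17
  folds <- sscbench:::make_folds(n, 5, cv_seed) # shared partition (input, not oracle)

  # ---- independent oracle: Krylov-closed-form PLS + explicit elimination ----
  krylov_cv <- function(Xk, yk, lv) {
    press <- 0
    for (f in folds) {
      bt <- pls_krylov_coef(Xk[-f, , drop = FALSE], yk[-f], lv)
      icept <- mean(yk[-f]) - sum(colMeans(Xk[-f, , drop = FALSE]) * bt)
      press <- press + sum((Xk[f, , drop = FALSE] %*% bt + icept - yk[f])^2)
    }
    sqrt(press / n)
  }
  best <- list(rmsecv = Inf)
  for (lv in seq_len(max_lv)) {
    kept <- seq_len(p)
    repeat {
      r <- krylov_cv(X[, kept, drop = FALSE], y, lv)
      better <- r < best$rmsecv ||
        (r == best$rmsecv &&
           (p - length(kept) > p - length(best$kept) ||
              (length(kept) == length(best$kept) && lv < best$lv)))
      if (better) best <- list(rmsecv = r, lv = lv, kept = kept)
      if (length(kept) <= lv) break
      b <- pls_krylov_coef(X[, kept, drop = FALSE], y,
                           min(lv, length(kept) - 1))
      drop_local <- order(abs(b), seq_along(b))[1]
      kept <- kept[-drop_local]
    }
  }

  fsr <- wrapper_select(X, y, max_lv = max_lv, cv_seed = cv_seed)
  expect_equal(fsr$n_lv, best$lv)
  expect_equal(which(fsr$retained_mask), best$kept)
  expect_equal(fsr$rmsecv, best$rmsecv, tolerance = 1e-8)
  expect_equal(fsr$n_discarded, p - length(best$kept))
})

test_that("selected RMSECV dominates the all-features model at every #LV", {
  set.seed(5)
  X <- matrix(rnorm(70 * 15), 70, 15)
  y <- X[, 1] - X[, 9] + rnorm(70, 0, 0.4)
  fsr <- wrapper_select(X, y, max_lv = 4, cv_seed = 9)
  surf <- fsr$rmsecv_surface
  full <- surf[surf$n_removed == 0, ]
  expect_true(all(fsr$rmsecv <= full$rmsecv + 1e-12))
})

test_that("noise-only response yields RMSECV near sd(y)", {
  set.seed(31)
  X <- matrix(rnorm(80 * 10), 80, 10)
  y <- rnorm(80)
  fsr <- wrapper_select(X, y, max_lv = 3, cv_seed = 2)
  expect_lt(abs(fsr$rmsecv - sd(y)), 0.35 * sd(y))
})

test_that("same cv_seed reproduces the bookkeeping exactly", {
  set.seed(77)
  X <- matrix(rnorm(50 * 8), 50, 8)
  y <- X[, 2] + rnorm(50, 0, 0.2)
  a <- wrapper_select(X, y, max_lv = 2, cv_seed = 42)
  b <- wrapper_select(X, y, max_lv = 2, cv_seed = 42)
  expect_identical(a[c("retained_mask", "n_discarded", "n_lv", "rmsecv")],
                   b[c("retained_mask", "n_discarded", "n_lv", "rmsecv")])
})

test_that("apply_selection drops masked columns, keeps augmented, matches by label", {
  pop <- tiny_population(n_fruits = 25, seed = 14)
  fm <- thin_features(
    build_data_type(pop, preproc_spec("absorbance", augmented = TRUE)), 30L)
  cal <- fm_rows(fm, 1:40)
  fsr <- wrapper_select(cal$X, cal$y, max_lv = 3, cv_seed = 1,
                        is_spectral = cal$is_spectral)
  out <- apply_selection(fm, fsr)
  expect_equal(sum(out$is_spectral), sum(fsr$retained_mask))
  expect_true(all(c("temperature", "size") %in% out$feature_labels))

  # all-true mask is the identity on spectral columns
  fsr_id <- fsr
  fsr_id$retained_mask[] <- TRUE
  expect_equal(apply_selection(fm, fsr_id)$X, fm$X)

  # a mask learned on one partition applies to another with the same labels
  other <- fm_rows(fm, 41:50)
  expect_equal(sum(apply_selection(other, fsr)$is_spectral),
               sum(fsr$retained_mask))

  # label mismatch is an error
  fm2 <- thin_features(
    build_data_type(pop, preproc_spec("absorbance", augmented = TRUE)), 40L)
  expect_error(apply_selection(fm2, fsr), "labels")
})

test_that("retained wavelengths concentrate on planted informative bands", {
  # single-condition population: no scatter/temperature/drift nuisance, so
  # off-band wavelengths carry nothing but noise
  cfg <- generator_config(
    n_fruits = 120, seed = 55,
    scatter_slope_per_mm = 0,
    temp_regimes = tibble::tibble(mean_C = 20, sd_C = 1, weight = 1),
    drift_ssc_offset = c(A = 0, B = 0, C = 0, D = 0, E = 0),
    drift_baseline_tilt = c(A = 0, B = 0, C = 0, D = 0, E = 0),
    drift_size_extremes_E = FALSE
  )
  pop <- generate_population(cfg)
  fm <- thin_features(build_data_type(pop, preproc_spec("absorbance")), 8L)
  fsr <- wrapper_select(fm$X, fm$y, max_lv = 8, cv_seed = 4,
                        is_spectral = fm$is_spectral)
  kept_wl <- fm$wavelengths[fm$is_spectral][fsr$retained_mask]
  bands <- cfg$band_library[cfg$band_library$kind != "water", ]
  near_band <- vapply(kept_wl, function(w) {
    any(abs(w - bands$center_nm) <= 2 * bands$width_nm)
  }, TRUE)
  expect_gte(mean(near_band), 0.8)
})
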