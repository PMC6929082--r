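# Independent oracles and small fixture builders used across the suite.

# PLS1 coefficients via the Krylov-subspace closed form: the k-component PLS1
# solution is the least-squares fit of centered y on centered X restricted to
# the Krylov space span{X'y, (X'X)X'y, ..., (X'X)^(k-1) X'y}. This route never
# touches the package's NIPALS loop.
pls_krylov_coef <- function(X, y, k) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  S <- crossprod(Xc)          # X'X
  v <- crossprod(Xc, yc)[, 1] # X'y
  K <- matrix(0, ncol(X), k)
  K[, 1] <- v
  if (k > 1) for (j in 2:k) K[, j] <- S %*% K[, j - 1]
  Q <- qr.Q(qr(K))            # orthonormal Krylov basis
  A <- crossprod(Q, S %*% Q)
  b <- crossprod(Q, v)
  beta <- Q %*% solve(A, b)
  as.vector(beta)
}

# Local least-squares polynomial derivative at interior point i: fit a
# polynomial of degree `deg` to the window around i, return the m-th
# derivative of the fit at the window center (per unit index).
local_polyfit_deriv <- function(x, i, window, deg, m) {
  h <- (window - 1) / 2
  idx <- (i - h):(i + h)
  t <- idx - i
  fit <- lm(x[idx] ~ poly(t, deg, raw = TRUE))
  factorial(m) * coef(fit)[[m + 1]]
}

# A small synthetic population shared by several tests.
tiny_population <- function(n_fruits = 40, seed = 101, ...) {
  generate_population(generator_config(n_fruits = n_fruits, seed = seed, ...))
}

# A noise-free, single-condition configuration (no temperature/size/drift
# confounds) used when a test needs exact band arithmetic.
clean_config <- function(n_fruits = 20, seed = 5, ...) {
  generator_config(
    n_fruits = n_fruits, seed = seed,
    noise_sd = 0, scatter_slope_per_mm = 0,
    temp_regimes = tibble::tibble(mean_C = 20, sd_C = 0, weight = 1),
    temp_range_C = c(4.7, 39),
    drift_ssc_offset = c(A = 0, B = 0, C = 0, D = 0, E = 0),
    drift_baseline_tilt = c(A = 0, B = 0, C = 0, D = 0, E = 0),
    drift_size_extremes_E = FALSE,
    ...
  )
}
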