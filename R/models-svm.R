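# RBF-kernel support-vector regression with analytic hyperparameter seeding
# and a restrained randomized search.
#
# The fitting backend is libsvm via e1071; the hyperparameter scheme (analytic
# C / epsilon / gamma estimates + coordinate-wise randomized search in
# [0.001 * P_th, 3 * P_th]) is implemented here. Inputs are expected on the
# [-1, 1]-ish scale produced by scale_for_svm().

#' Theoretical SVR hyperparameters
#'
#' Analytic starting values:
#' * `C_th = max(|mean(y) + 3 sd(y)|, |mean(y) - 3 sd(y)|)` from the response
#'   distribution,
#' * `epsilon_th = 3 * sigma_noise * sqrt(ln(n) / n)` where `sigma_noise^2` is
#'   the k-nearest-neighbour residual MSE with the small-sample correction
#'   `n^(1/5) k / (n^(1/5) k - 1)`,
#' * `gamma_th` maximises the variance of the off-diagonal RBF kernel entries
#'   over a logarithmic gamma grid (kernel similarity diversity).
#'
#' @param X Scaled calibration features (see [scale_for_svm()]).
#' @param y SSC vector (degrees Brix).
#' @param k_neighbors Neighbours for the noise estimate (default 5).
#' @param gamma_grid Log-spaced candidate grid for `gamma_th`.
#' @param max_pairs Kernel-variance estimation uses at most this many random
#'   row pairs (seeded internally from the data size for determinism).
#' @param epsilon_floor Lower bound applied to `epsilon_th` (the zero-noise
#'   limit would give 0, which libsvm accepts but the search interval would
#'   degenerate).
#' @return Named numeric vector `c(C_th, gamma_th, epsilon_th)`.
#' @export
svm_theoretical_params <- function(X, y, k_neighbors = 5L,
                                   gamma_grid = 10^seq(-4, 2, length.out = 25),
                                   max_pairs = 500L,
                                   epsilon_floor = 1e-4) {
  d <- as_xy(X, y)
  X <- d$X; y <- d$y
  n <- nrow(X)
  stopifnot(n > k_neighbors)
  sy <- sd(y)
  if (sy == 0) abort("response has zero variance")
  c_th <- max(abs(mean(y) + 3 * sy), abs(mean(y) - 3 * sy))

  # k-NN in-sample residual MSE with small-sample correction
  yhat <- knn_regress(X, y, k_neighbors)
  corr <- n^(1 / 5) * k_neighbors / (n^(1 / 5) * k_neighbors - 1)
  sigma2 <- corr * mean((y - yhat)^2)
  eps_th <- max(3 * sqrt(sigma2) * sqrt(log(n) / n), epsilon_floor)

  # gamma: maximise variance of off-diagonal RBF kernel entries
  pair_seed <- derive_seed(n + ncol(X), "svm-gamma-pairs")
  pairs <- with_seed(pair_seed, {
    i <- sample.int(n, min(max_pairs, n * (n - 1) / 2), replace = TRUE)
    j <- sample.int(n, length(i), replace = TRUE)
    bad <- i == j
    j[bad] <- (j[bad] %% n) + 1L
    cbind(i, j)
  })
  d2 <- rowSums((X[pairs[, 1], , drop = FALSE] -
                   X[pairs[, 2], , drop = FALSE])^2)
  if (all(d2 == 0)) abort("all rows identical: kernel variance is degenerate")
  kv <- vapply(gamma_grid, function(g) var(exp(-g * d2)), 0)
  gamma_th <- gamma_grid[which.max(kv)]
  c(C_th = c_th, gamma_th = gamma_th, epsilon_th = eps_th)
}

#' In-sample k-NN regression predictions (self included)
#' @noRd
knn_regress <- function(X, y, k) {
  n <- nrow(X)
  G <- tcrossprod(X)
  sq <- diag(G)
  D2 <- outer(sq, sq, "+") - 2 * G
  apply(D2, 1, function(dr) mean(y[order(dr)[seq_len(k)]]))
}

#' Fit an RBF SVR with given hyperparameters
#' @noRd
fit_svr_raw <- function(X, y, C, gamma, epsilon) {
  e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
             cost = C, gamma = gamma, epsilon = epsilon, scale = FALSE)
}

#' Optimize and fit the SVR calibration engine
#'
#' Three coordinate passes over (C, gamma, epsilon), in that order. In each
#' pass the other two hyperparameters are frozen (at their theoretical values
#' or at previously optimized ones), `n_candidates` values are drawn uniformly
#' from `[0.001 * P_th, 3 * P_th]`, the incumbent value is evaluated alongside
#' them, and the 5-fold cross-validated RMSE minimiser is kept. The reported
#' RMSEC is the best CV RMSE of the final pass.
#'
#' @param X Scaled calibration features (matrix or `feature_matrix` already
#'   passed through [scale_for_svm()]).
#' @param y SSC vector.
#' @param theoretical Optional named vector from [svm_theoretical_params()];
#'   computed from the data when `NULL`.
#' @param n_candidates Random candidates per pass (default 30).
#' @param cv_folds CV folds (default 5).
#' @param seed Seed for candidate draws and fold partition.
#' @param interval_factor Search interval `[f1 * P_th, f2 * P_th]`.
#' @param k_neighbors Passed to [svm_theoretical_params()].
#' @return A `calibration_model` of kind `"SVM"`; `hyperparams` holds the
#'   final `C`, `gamma`, `epsilon` and the theoretical triplet.
#' @export
svm_optimize <- function(X, y = NULL, theoretical = NULL, n_candidates = 30L,
                         cv_folds = 5L, seed = 1L,
                         interval_factor = c(0.001, 3), k_neighbors = 5L) {
  d <- as_xy(X, y)
  X <- d$X; y <- d$y
  n <- nrow(X)
  if (is.null(theoretical)) {
    theoretical <- svm_theoretical_params(X, y, k_neighbors = k_neighbors)
  }
  th <- c(C = unname(theoretical["C_th"]),
          gamma = unname(theoretical["gamma_th"]),
          epsilon = unname(theoretical["epsilon_th"]))
  folds <- make_folds(n, cv_folds, derive_seed(seed, "svm-cv"))
  current <- th
  final_rmsec <- NA_real_
  for (coord in c("C", "gamma", "epsilon")) {
    lo <- interval_factor[1] * th[coord]
    hi <- interval_factor[2] * th[coord]
    cand <- with_seed(derive_seed(seed, paste0("svm-rgs-", coord)),
                      runif(n_candidates, lo, hi))
    cand <- c(unname(current[coord]), cand) # incumbent always evaluated
    scores <- vapply(cand, function(v) {
      pars <- current
      pars[coord] <- v
      tryCatch(
        cv_rmse_generic(
          X, y, folds,
          function(Xt, yt) fit_svr_raw(Xt, yt, pars["C"], pars["gamma"],
                                       pars["epsilon"]),
          function(m, Xv) predict(m, Xv)
        ),
        error = function(e) NA_real_
      )
    }, 0)
    if (all(is.na(scores))) {
      abort(sprintf("all SVR candidates failed while optimizing %s", coord))
    }
    best <- which.min(scores)
    current[coord] <- cand[best]
    final_rmsec <- scores[best]
  }
  fit <- fit_svr_raw(X, y, current["C"], current["gamma"], current["epsilon"])
  new_calibration_model(
    kind = "SVM",
    hyperparams = list(C = unname(current["C"]),
                       gamma = unname(current["gamma"]),
                       epsilon = unname(current["epsilon"]),
                       theoretical = th,
                       n_candidates = n_candidates,
                       interval_factor = interval_factor),
    fit = fit, rmsec = final_rmsec, n_cal = n,
    feature_labels = colnames(X),
    predict_fun = function(Xn) as.vector(predict(fit, Xn))
  )
}
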