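# Calibration engines: shared contract + the two linear models.
#
# Every engine returns a `calibration_model`: predictions come out in degrees
# Brix and any input scaling uses *stored calibration statistics only* (no
# validation leakage).

#' @noRd
new_calibration_model <- function(kind, hyperparams, fit, rmsec, n_cal,
                                  feature_labels, predict_fun) {
  structure(list(kind = kind, hyperparams = hyperparams, fit = fit,
                 rmsec = rmsec, n_cal = n_cal,
                 feature_labels = feature_labels,
                 predict_fun = predict_fun),
            class = "calibration_model")
}

#' Predict SSC from a fitted calibration model
#'
#' @param object A `calibration_model`.
#' @param newdata A numeric matrix or a `feature_matrix` with the same feature
#'   columns the model was calibrated on.
#' @param ... Unused.
#' @return Numeric vector of SSC predictions in degrees Brix.
#' @export
predict.calibration_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$X else
    as.matrix(newdata)
  if (!is.null(object$feature_labels) && !is.null(colnames(X)) &&
      !identical(colnames(X), object$feature_labels)) {
    abort("feature columns of `newdata` do not match the calibration set")
  }
  object$predict_fun(X)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s: %d calibration samples, RMSEC = %.3f Brix\n",
              x$kind, x$n_cal, x$rmsec))
  invisible(x)
}

#' One-row summary of a calibration model
#' @param x A `calibration_model`.
#' @param ... Unused.
#' @method glance calibration_model
#' @export
glance.calibration_model <- function(x, ...) {
  tibble(kind = x$kind, n_cal = x$n_cal, rmsec = x$rmsec,
         n_features = length(x$feature_labels))
}

#' Coefficients / hyperparameters of a calibration model
#'
#' For the linear engines (PLS, MLR) returns one row per feature with its
#' regression coefficient; for SVM/MLP returns the hyperparameters.
#' @param x A `calibration_model`.
#' @param ... Unused.
#' @method tidy calibration_model
#' @export
tidy.calibration_model <- function(x, ...) {
  if (x$kind %in% c("PLS", "MLR")) {
    tibble(term = c("(Intercept)", x$feature_labels),
           estimate = x$fit$coef_full)
  } else {
    tibble(term = names(unlist(x$hyperparams)),
           estimate = unname(unlist(x$hyperparams)))
  }
}

#' @noRd
as_xy <- function(X, y = NULL) {
  if (inherits(X, "feature_matrix")) list(X = X$X, y = X$y)
  else list(X = as.matrix(X), y = y)
}

#' Generic k-fold CV RMSE for an arbitrary fit/predict pair
#' @noRd
cv_rmse_generic <- function(X, y, folds, fit_fun, predict_fun) {
  press <- 0
  for (f in folds) {
    m <- fit_fun(X[-f, , drop = FALSE], y[-f])
    press <- press + sum((predict_fun(m, X[f, , drop = FALSE]) - y[f])^2)
  }
  sqrt(press / length(y))
}

#' Fit the PLS calibration engine
#'
#' Fits PLS with `n_lv` latent variables; the reported RMSEC is the 10-fold
#' cross-validation RMSE on the calibration set (a more conservative figure
#' than the in-sample residual RMSE).
#'
#' @param X Calibration features (matrix or `feature_matrix`).
#' @param y SSC vector (ignored when `X` is a `feature_matrix`).
#' @param n_lv Latent-variable count (typically from [wrapper_select()]).
#' @param cv_folds Folds for the RMSEC protocol (default 10).
#' @param cv_seed Seed for the RMSEC fold partition.
#' @return A `calibration_model` of kind `"PLS"`.
#' @export
fit_pls <- function(X, y = NULL, n_lv, cv_folds = 10L, cv_seed = 1L) {
  d <- as_xy(X, y)
  fit <- pls_fit(d$X, d$y, n_lv)
  folds <- make_folds(nrow(d$X), cv_folds, cv_seed)
  rmsec <- cv_rmse_generic(
    d$X, d$y, folds,
    function(Xt, yt) pls_fit(Xt, yt, n_lv),
    function(m, Xv) predict(m, Xv, ncomp = min(n_lv, m$ncomp))
  )
  b <- fit$coefs[, min(n_lv, fit$ncomp)]
  fit$coef_full <- c(fit$y_mean - sum(fit$x_mean * b), b)
  new_calibration_model(
    kind = "PLS", hyperparams = list(n_lv = n_lv), fit = fit,
    rmsec = rmsec, n_cal = nrow(d$X), feature_labels = colnames(d$X),
    predict_fun = function(Xn) {
      as.vector(predict(fit, Xn, ncomp = min(n_lv, fit$ncomp)))
    }
  )
}

#' Fit the MLR calibration engine
#'
#' Ordinary least squares with intercept. Requires strictly more samples than
#' features (otherwise the coefficients are not reliably computable and the
#' engine refuses with an "MLR not applicable" error, which benchmark cells
#' record as skipped). Rank deficiency (e.g., duplicated columns) is surfaced
#' as an error, never silently dropped.
#'
#' @inheritParams fit_pls
#' @return A `calibration_model` of kind `"MLR"`.
#' @export
fit_mlr <- function(X, y = NULL, cv_folds = 10L, cv_seed = 1L) {
  d <- as_xy(X, y)
  n <- nrow(d$X); p <- ncol(d$X)
  if (n <= p) {
    abort(sprintf(
      "MLR not applicable: %d features but only %d samples (need n_samples > n_features)",
      p, n), class = "sscbench_mlr_not_applicable")
  }
  ols <- function(Xt, yt) {
    qr_ <- qr(cbind(`(Intercept)` = 1, Xt))
    if (qr_$rank < ncol(Xt) + 1L) {
      abort("MLR design matrix is rank deficient (collinear features)")
    }
    qr.coef(qr_, yt)
  }
  beta <- ols(d$X, d$y)
  folds <- make_folds(n, cv_folds, cv_seed)
  rmsec <- cv_rmse_generic(
    d$X, d$y, folds, ols,
    function(b, Xv) cbind(1, Xv) %*% b
  )
  new_calibration_model(
    kind = "MLR", hyperparams = list(), fit = list(coef_full = beta),
    rmsec = rmsec, n_cal = n, feature_labels = colnames(d$X),
    predict_fun = function(Xn) as.vector(cbind(1, Xn) %*% beta)
  )
}
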