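# PLS1 regression core.
#
# NIPALS-style component extraction for a univariate response, with X
# deflation and regression coefficients reconstructed in the original feature
# space for every component count 1..ncomp (needed both for wavelength ranking
# and for evaluating a whole RMSECV-vs-#LV column from one fit).

#' Fit a PLS1 regression
#'
#' @param X Numeric matrix (n x p).
#' @param y Numeric response vector (length n).
#' @param ncomp Number of latent variables to extract.
#' @return A list with `coefs` (p x ncomp matrix; column a = coefficients of
#'   the a-component model in the original feature space), `x_mean`, `y_mean`,
#'   `ncomp` (actually extracted; extraction stops early if X is exhausted).
#' @export
pls_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, ncomp >= 1)
  ncomp <- min(ncomp, n - 1L, p)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Rm <- matrix(0, p, ncomp) # R = W (P'W)^-1, built incrementally
  qv <- numeric(ncomp)
  coefs <- matrix(0, p, ncomp)
  B <- numeric(p)
  a <- 0L
  for (h in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)[, 1]
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break # X carries no further covariance with y
    w <- w / wn
    t_ <- Xc %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    pvec <- crossprod(Xc, t_)[, 1] / tt
    qh <- sum(yc * t_) / tt
    Xc <- Xc - t_ %*% t(pvec)
    yc <- yc - qh * t_
    W[, h] <- w; P[, h] <- pvec; qv[h] <- qh
    r <- w
    if (h > 1L) {
      r <- as.vector(w - Rm[, seq_len(h - 1L), drop = FALSE] %*%
                       crossprod(P[, seq_len(h - 1L), drop = FALSE], w))
    }
    Rm[, h] <- r
    B <- B + r * qh
    coefs[, h] <- B
    a <- h
  }
  if (a == 0L) abort("PLS failed: X has no covariance with y")
  if (a < ncomp) coefs[, (a + 1L):ncomp] <- coefs[, a] # saturated
  structure(list(coefs = coefs, x_mean = x_mean, y_mean = y_mean,
                 ncomp = ncomp, ncomp_extracted = a),
            class = "pls_fit")
}

#' Predict from a PLS fit
#'
#' @param object A [pls_fit()] result.
#' @param newdata Matrix of predictors.
#' @param ncomp Component count(s) to predict with; default all extracted.
#' @param ... Unused.
#' @return If `ncomp` is scalar, a numeric vector; otherwise an
#'   n x length(ncomp) matrix.
#' @export
predict.pls_fit <- function(object, newdata, ncomp = object$ncomp, ...) {
  Xc <- sweep(as.matrix(newdata), 2, object$x_mean)
  out <- Xc %*% object$coefs[, ncomp, drop = FALSE] + object$y_mean
  if (length(ncomp) == 1L) out[, 1] else out
}

#' Cross-validated RMSE of PLS for every component count
#'
#' One fit per fold evaluates the full 1..max_lv column of the RMSECV surface.
#'
#' @param X,y Data.
#' @param max_lv Maximum number of latent variables.
#' @param folds List of validation index vectors (from [make_folds()]).
#' @return Numeric vector of RMSECV (same units as `y`), one entry per #LV
#'   1..max_lv. Component counts beyond what the data can support repeat the
#'   saturated model's error.
#' @noRd
pls_cv_rmse <- function(X, y, max_lv, folds) {
  press <- numeric(max_lv)
  for (f in folds) {
    fit <- pls_fit(X[-f, , drop = FALSE], y[-f], max_lv)
    pred <- predict(fit, X[f, , drop = FALSE], ncomp = seq_len(max_lv))
    if (is.null(dim(pred))) pred <- matrix(pred, ncol = 1L)
    press <- press + colSums((pred - y[f])^2)
  }
  sqrt(press / length(y))
}
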