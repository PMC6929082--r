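# Single-hidden-layer perceptron regressor.
#
# Architecture and training rules: hidden neurons = ceiling(n_features / 3),
# ReLU activation, Adam optimizer (lr 1e-3), minibatches of 16, MSE loss, at
# most 300 epochs with early stopping (patience 10) on an internal 20% test
# split of the calibration set. Inputs are standardized and the response
# standardized (mean/sd) with *calibration* statistics; predictions are
# rescaled to degrees Brix. The output layer is initialized near zero so the
# network starts at the calibration mean and learns the signal instead of
# first unlearning a large random output. The engine trains `n_repeats` networks from different
# seeded initializations/shuffles and predicts with the average of their
# outputs.

#' MLP training configuration
#'
#' @param n_features Number of input features (sets the hidden-layer size to
#'   `ceiling(n_features / 3)` unless overridden).
#' @param hidden_neurons Hidden-layer width.
#' @param batch_size Minibatch size (default 16).
#' @param max_epochs Maximum training epochs (default 300).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param internal_test_fraction Share of the calibration set held out as the
#'   internal early-stopping split (default 0.2).
#' @param n_repeats Number of independently initialized fits averaged
#'   (default 10).
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(n_features,
                       hidden_neurons = ceiling(n_features / 3),
                       batch_size = 16L, max_epochs = 300L, patience = 10L,
                       learning_rate = 1e-3,
                       internal_test_fraction = 0.2, n_repeats = 10L) {
  structure(list(hidden_neurons = as.integer(hidden_neurons),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate,
                 internal_test_fraction = internal_test_fraction,
                 n_repeats = as.integer(n_repeats)),
            class = "mlp_config")
}

#' Train one network (Adam + ReLU + early stopping)
#' @return list(W1, b1, W2, b2)
#' @noRd
train_mlp_once <- function(X, yz, config, seed) {
  n <- nrow(X); p <- ncol(X); h <- config$hidden_neurons
  with_seed(seed, {
    n_test <- max(1L, round(config$internal_test_fraction * n))
    test_idx <- sample.int(n, n_test)
    Xtr <- X[-test_idx, , drop = FALSE]; ytr <- yz[-test_idx]
    Xte <- X[test_idx, , drop = FALSE]; yte <- yz[test_idx]
    ntr <- nrow(Xtr)

    W1 <- matrix(rnorm(p * h, 0, sqrt(2 / p)), p, h) # He init for ReLU
    b1 <- rep(0, h)
    W2 <- matrix(rnorm(h, 0, 0.05), h, 1) # near-zero output init
    b2 <- mean(ytr)
    params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    mom <- lapply(params, function(p_) p_ * 0)
    vel <- lapply(params, function(p_) p_ * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    lr <- config$learning_rate
    step <- 0L
    best <- list(loss = Inf, params = params)
    wait <- 0L

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(ntr)
      starts <- seq(1L, ntr, by = config$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, ntr)]
        Xb <- Xtr[idx, , drop = FALSE]; yb <- ytr[idx]
        m <- length(idx)
        Z1 <- sweep(Xb %*% params$W1, 2, params$b1, "+")
        H <- Z1 * (Z1 > 0)
        pred <- as.vector(H %*% params$W2) + params$b2
        err <- pred - yb                       # d(MSE)/d(pred) * m / 2
        g_pred <- 2 * err / m
        grads <- list(
          W1 = NULL, b1 = NULL,
          W2 = crossprod(H, g_pred),
          b2 = sum(g_pred)
        )
        gH <- tcrossprod(g_pred, params$W2[, 1]) * (Z1 > 0)
        grads$W1 <- crossprod(Xb, gH)
        grads$b1 <- colSums(gH)
        step <- step + 1L
        for (nm in names(params)) {
          mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grads[[nm]]
          vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grads[[nm]]^2
          mhat <- mom[[nm]] / (1 - beta1^step)
          vhat <- vel[[nm]] / (1 - beta2^step)
          params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      Z1 <- sweep(Xte %*% params$W1, 2, params$b1, "+")
      te_pred <- as.vector((Z1 * (Z1 > 0)) %*% params$W2) + params$b2
      te_loss <- mean((te_pred - yte)^2)
      if (!is.finite(te_loss)) return(NULL) # caller restarts with next seed
      if (te_loss < best$loss - 1e-10) {
        best <- list(loss = te_loss, params = params)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    best$params
  })
}

#' @noRd
mlp_forward <- function(params, X) {
  Z1 <- sweep(X %*% params$W1, 2, params$b1, "+")
  as.vector((Z1 * (Z1 > 0)) %*% params$W2) + params$b2
}

#' Fit the MLP calibration engine
#'
#' @param X Calibration features (matrix or `feature_matrix`); standardization
#'   is handled internally with stored calibration statistics.
#' @param y SSC vector (ignored when `X` is a `feature_matrix`).
#' @param config An [mlp_config()]; defaults derived from `ncol(X)`.
#' @param seed Master seed; repeat r uses a seed derived from it.
#' @return A `calibration_model` of kind `"MLP"`. `rmsec` is the mean over
#'   repeats of the in-sample calibration RMSE (degrees Brix).
#' @export
fit_mlp <- function(X, y = NULL, config = NULL, seed = 1L) {
  d <- as_xy(X, y)
  X <- d$X; y <- d$y
  n <- nrow(X); p <- ncol(X)
  if (is.null(config)) config <- mlp_config(p)
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, sd_pop)
  x_sd[x_sd == 0] <- 1
  y_mean <- mean(y)
  y_sd <- sd_pop(y)
  if (y_sd == 0) y_sd <- 1
  Xs <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  yz <- (y - y_mean) / y_sd

  nets <- vector("list", config$n_repeats)
  rmsec_r <- numeric(config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    attempt <- 0L
    repeat {
      net <- train_mlp_once(Xs, yz, config,
                            derive_seed(seed, paste0("mlp-", r, "-", attempt)))
      if (!is.null(net)) break
      attempt <- attempt + 1L
      if (attempt > 5L) abort("MLP training diverged repeatedly")
    }
    nets[[r]] <- net
    pred <- mlp_forward(net, Xs) * y_sd + y_mean
    rmsec_r[r] <- rms(pred - y)
  }
  scaling <- list(x_mean = x_mean, x_sd = x_sd, y_mean = y_mean, y_sd = y_sd)
  predict_fun <- function(Xn) {
    Xn <- sweep(sweep(Xn, 2, scaling$x_mean), 2, scaling$x_sd, "/")
    preds <- vapply(nets, function(nt) mlp_forward(nt, Xn),
                    numeric(nrow(Xn)))
    if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
    rowMeans(preds) * scaling$y_sd + scaling$y_mean
  }
  new_calibration_model(
    kind = "MLP",
    hyperparams = list(hidden_neurons = config$hidden_neurons,
                       batch_size = config$batch_size,
                       max_epochs = config$max_epochs,
                       n_repeats = config$n_repeats,
                       learning_rate = config$learning_rate),
    fit = list(nets = nets, scaling = scaling),
    rmsec = mean(rmsec_r), n_cal = n, feature_labels = colnames(X),
    predict_fun = predict_fun
  )
}
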