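# PLS wrapper wavelength selection.
#
# Double loop: the outer loop sweeps the latent-variable count #LV, the inner
# loop eliminates one spectral feature at a time (lowest |PLS regression
# coefficient| first), recording the 5-fold RMSECV at every
# (#LV, n_removed) cell. The global RMSECV minimiser gives the retained
# wavelength mask and optimal #LV. Augmented temperature/size columns are
# always retained and never ranked.

#' Rank spectral features by PLS coefficient importance
#'
#' Fits a PLS regression with `n_lv` components on all columns of `X` and
#' returns the *spectral* feature indices ordered by increasing absolute
#' regression coefficient (first = least important). Ties are broken toward
#' the lower column index.
#'
#' @param X Feature matrix.
#' @param y Response (SSC, degrees Brix).
#' @param n_lv Number of latent variables.
#' @param is_spectral Logical per column; non-spectral (augmented) columns are
#'   excluded from the ranking. Default: all columns are spectral.
#' @return Integer vector of spectral column indices, least important first.
#' @export
rank_features <- function(X, y, n_lv, is_spectral = rep(TRUE, ncol(X))) {
  fit <- pls_fit(X, y, n_lv)
  b <- abs(fit$coefs[, min(n_lv, fit$ncomp)])
  sp <- which(is_spectral)
  sp[order(b[sp], sp)] # ascending |coef|; ties -> lower index first
}

#' PLS wrapper feature selection
#'
#' @param X Feature matrix (calibration samples only).
#' @param y SSC vector (degrees Brix).
#' @param max_lv Maximum latent-variable count swept by the outer loop
#'   (default 25).
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param cv_seed Seed for the fold partition; the same folds are used for
#'   every cell of the surface so cells are comparable.
#' @param is_spectral Logical per column of `X`; augmented columns (`FALSE`)
#'   are kept in every model but never eliminated.
#' @param recompute_ranking If `TRUE` (default) the coefficient ranking is
#'   recomputed after every removal (full wrapper); if `FALSE` the ranking is
#'   fixed once per #LV (cheaper).
#' @param min_spectral Inner loop stops when this many spectral features
#'   remain; default `NULL` stops at `#LV` features (model saturated).
#' @return A `feature_selection_result` with `retained_mask` (logical over
#'   spectral features), `n_discarded`, `n_lv`, `rmsecv` (the minimum, degrees
#'   Brix), `rmsecv_surface` (tibble with `n_lv`, `n_removed`, `rmsecv`),
#'   `cv_seed` and the feature labels.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60 * 8), 60, 8)
#' y <- 2 * X[, 3] + rnorm(60, 0, 0.1)
#' wrapper_select(X, y, max_lv = 2, cv_seed = 1)$n_lv
wrapper_select <- function(X, y, max_lv = 25L, cv_folds = 5L, cv_seed = 1L,
                           is_spectral = rep(TRUE, ncol(X)),
                           recompute_ranking = TRUE,
                           min_spectral = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(max_lv >= 1L, n >= cv_folds, length(y) == n)
  folds <- make_folds(n, cv_folds, cv_seed)
  sp_idx <- which(is_spectral)
  n_sp <- length(sp_idx)
  labels <- colnames(X) %||% as.character(seq_len(ncol(X)))

  surf <- list()
  best <- list(rmsecv = Inf, n_lv = NA_integer_, removed = integer())
  for (lv in seq_len(max_lv)) {
    removed <- integer() # spectral columns removed so far, in order
    stop_at <- max(min_spectral %||% lv, 1L)
    repeat {
      keep <- setdiff(seq_len(ncol(X)), removed)
      n_keep_sp <- sum(is_spectral[keep])
      feasible <- lv <= min(n - ceiling(n / cv_folds) - 1L, length(keep))
      rmsecv <- if (feasible) {
        pls_cv_rmse(X[, keep, drop = FALSE], y, lv, folds)[lv]
      } else NA_real_
      surf[[length(surf) + 1L]] <- c(lv, length(removed), rmsecv)
      if (!is.na(rmsecv)) {
        # tie rule: equal RMSECV -> prefer more features removed, then
        # fewer #LV (parsimony)
        better <- rmsecv < best$rmsecv ||
          (rmsecv == best$rmsecv &&
             (length(removed) > length(best$removed) ||
                (length(removed) == length(best$removed) && lv < best$n_lv)))
        if (better) best <- list(rmsecv = rmsecv, n_lv = lv, removed = removed)
      }
      if (n_keep_sp <= stop_at) break
      ord <- if (recompute_ranking || length(removed) == 0L) {
        keep_sp_order <- rank_features(X[, keep, drop = FALSE], y,
                                       min(lv, length(keep) - 1L, n - 1L),
                                       is_spectral[keep])
        keep[keep_sp_order]
      } else {
        setdiff(fixed_order, removed)
      }
      if (!recompute_ranking && length(removed) == 0L) fixed_order <- ord
      removed <- c(removed, ord[1L])
    }
  }
  surface <- tibble(
    n_lv = vapply(surf, `[`, 0, 1), n_removed = vapply(surf, `[`, 0, 2),
    rmsecv = vapply(surf, `[`, 0, 3)
  )
  if (!is.finite(best$rmsecv)) abort("no feasible (n_lv, removal) cell")
  retained_mask <- rep(TRUE, n_sp)
  retained_mask[match(best$removed, sp_idx)] <- FALSE
  structure(
    list(retained_mask = retained_mask,
         n_discarded = sum(!retained_mask),
         n_lv = best$n_lv, rmsecv = best$rmsecv,
         rmsecv_surface = surface, cv_seed = cv_seed,
         spectral_labels = labels[sp_idx],
         feature_labels = labels),
    class = "feature_selection_result"
  )
}

#' @export
print.feature_selection_result <- function(x, ...) {
  cat(sprintf(
    "<feature_selection_result> %d/%d wavelengths discarded, #LV = %d, RMSECV = %.3f Brix\n",
    x$n_discarded, length(x$retained_mask), x$n_lv, x$rmsecv))
  invisible(x)
}

#' Apply a feature-selection mask to a feature matrix
#'
#' Drops the masked-out spectral columns (matched by feature label, so a mask
#' learned on one partition can be applied to another with the same grid) and
#' keeps all augmented columns.
#'
#' @param fm A `feature_matrix`.
#' @param fsr A `feature_selection_result`.
#' @return A reduced `feature_matrix`.
#' @export
apply_selection <- function(fm, fsr) {
  stopifnot(inherits(fm, "feature_matrix"),
            inherits(fsr, "feature_selection_result"))
  sp_labels <- fm$feature_labels[fm$is_spectral]
  if (length(sp_labels) != length(fsr$retained_mask) ||
      !all(sp_labels == fsr$spectral_labels)) {
    abort("feature labels of mask and matrix do not match")
  }
  keep_sp <- sp_labels[fsr$retained_mask]
  keep <- fm$feature_labels %in% keep_sp | !fm$is_spectral
  new_feature_matrix(fm$X[, keep, drop = FALSE], fm$y,
                     fm$feature_labels[keep], fm$wavelengths[keep],
                     fm$is_spectral[keep], fm$meta, fm$spec, fm$scaling)
}

#' Tidy the RMSECV surface
#' @param x A `feature_selection_result`.
#' @param ... Unused.
#' @return Tibble `n_lv`, `n_removed`, `rmsecv`.
#' @method tidy feature_selection_result
#' @export
tidy.feature_selection_result <- function(x, ...) x$rmsecv_surface

#' @rdname tidy.feature_selection_result
#' @method glance feature_selection_result
#' @export
glance.feature_selection_result <- function(x, ...) {
  tibble(n_discarded = x$n_discarded, n_retained = sum(x$retained_mask),
         n_lv = x$n_lv, rmsecv = x$rmsecv, cv_seed = x$cv_seed)
}

#' Heatmap of the wrapper RMSECV surface
#'
#' @param object A `feature_selection_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot feature_selection_result
#' @export
autoplot.feature_selection_result <- function(object, ...) {
  ggplot(object$rmsecv_surface,
         aes(x = .data$n_removed, y = .data$n_lv, fill = .data$rmsecv)) +
    geom_tile() +
    scale_fill_viridis_c(name = "RMSECV (°Brix)", na.value = "grey85") +
    labs(x = "wavelengths removed", y = "#LV",
         title = "PLS wrapper selection surface") +
    theme_minimal()
}

#' Serialize a feature-selection result to JSON
#'
#' @param fsr A `feature_selection_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(fsr, path) {
  jsonlite::write_json(
    list(retained_wavelengths = fsr$spectral_labels[fsr$retained_mask],
         n_discarded = fsr$n_discarded, n_lv = fsr$n_lv,
         rmsecv = fsr$rmsecv, cv_seed = fsr$cv_seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
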