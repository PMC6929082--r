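# Preprocessing: the 24-recipe grid.
#
# Pipeline order is fixed: absorbance -> optional Savitzky-Golay derivative on
# the full grid -> trim 75 points per edge -> optional restriction to
# wavelengths >= 730 nm (noChl; applied *before* SNV so the SNV statistics use
# only retained wavelengths) -> optional SNV -> optional appended temperature
# and size columns.

#' Preprocessing recipe
#'
#' One of the 24 data-type recipes: base transform (absorbance or its 1st/2nd
#' Savitzky-Golay derivative) x optional SNV x optional temperature/size
#' augmentation x full / chlorophyll-free spectral range.
#'
#' @param base `"absorbance"`, `"deriv1"` or `"deriv2"`.
#' @param snv Apply Standard Normal Variate per spectrum?
#' @param augmented Append temperature and size as extra features?
#' @param spectral_range `"full"` or `"noChl"` (drop wavelengths below
#'   `chl_cutoff_nm`).
#' @param sg_window Savitzky-Golay window (odd, default 51 points).
#' @param sg_polyorder Savitzky-Golay polynomial degree (default 2).
#' @param trim_points Points trimmed from each spectral edge (default 75).
#' @param chl_cutoff_nm Chlorophyll cutoff (default 730 nm).
#' @return A `preproc_spec` object.
#' @export
#' @examples
#' preproc_spec("deriv1", snv = TRUE, augmented = TRUE)
preproc_spec <- function(base = c("absorbance", "deriv1", "deriv2"),
                         snv = FALSE, augmented = FALSE,
                         spectral_range = c("full", "noChl"),
                         sg_window = 51L, sg_polyorder = 2L,
                         trim_points = 75L, chl_cutoff_nm = 730) {
  base <- match.arg(base)
  spectral_range <- match.arg(spectral_range)
  if (sg_window %% 2 != 1 || sg_window <= sg_polyorder) {
    abort("`sg_window` must be odd and greater than `sg_polyorder`")
  }
  if (2L * trim_points >= 1024L) abort("`trim_points` leaves no spectrum")
  spec <- list(base = base, snv = isTRUE(snv), augmented = isTRUE(augmented),
               spectral_range = spectral_range,
               sg_window = as.integer(sg_window),
               sg_polyorder = as.integer(sg_polyorder),
               trim_points = as.integer(trim_points),
               chl_cutoff_nm = chl_cutoff_nm)
  class(spec) <- "preproc_spec"
  spec
}

#' Data-type name of a recipe
#'
#' Naming convention: `abs`, `abs_snv`, `abs1d`, `abs1d_snv`, `abs2d`,
#' `abs2d_snv`, with a trailing `2` when temperature and size are appended
#' (e.g., `abs1d_snv2`).
#'
#' @param spec A [preproc_spec()].
#' @return Character scalar.
#' @export
data_type_name <- function(spec) {
  stopifnot(inherits(spec, "preproc_spec"))
  nm <- switch(spec$base, absorbance = "abs", deriv1 = "abs1d", deriv2 = "abs2d")
  if (spec$snv) nm <- paste0(nm, "_snv")
  if (spec$augmented) nm <- paste0(nm, "2")
  nm
}

#' @export
print.preproc_spec <- function(x, ...) {
  cat(sprintf("<preproc_spec> %s (%s range)\n", data_type_name(x),
              x$spectral_range))
  invisible(x)
}

#' The full 24-recipe preprocessing grid
#'
#' @param spectral_ranges Ranges to include (default both).
#' @param ... Passed to [preproc_spec()] (e.g., a different `sg_window`).
#' @return List of 24 (or 12 per range) [preproc_spec()] objects.
#' @export
preproc_grid <- function(spectral_ranges = c("full", "noChl"), ...) {
  grid <- expand.grid(base = c("absorbance", "deriv1", "deriv2"),
                      snv = c(FALSE, TRUE), augmented = c(FALSE, TRUE),
                      spectral_range = spectral_ranges,
                      stringsAsFactors = FALSE)
  purrr::pmap(grid, function(base, snv, augmented, spectral_range) {
    preproc_spec(base = base, snv = snv, augmented = augmented,
                 spectral_range = spectral_range, ...)
  })
}

#' Reflectance to absorbance
#'
#' Elementwise `log10(1/R)`.
#'
#' @param R Reflectance vector or matrix, strictly positive.
#' @return Same shape as `R`.
#' @export
#' @examples
#' reflectance_to_absorbance(c(1, 0.1))
reflectance_to_absorbance <- function(R) {
  if (any(!is.finite(R)) || any(R <= 0)) {
    abort("reflectance must be strictly positive and finite")
  }
  -log10(R)
}

#' Savitzky-Golay smoothed derivative
#'
#' Least-squares local-polynomial derivative per unit grid index (the detector
#' pitch is treated as uniform). Exact for polynomials of degree up to the fit
#' degree. Interior points use the central least-squares filter; the first and
#' last half-window points use the position-specific edge filters (the
#' `signal::sgolayfilt` convention -- those points are trimmed away downstream
#' anyway). Accepts a vector (one spectrum) or a matrix (one spectrum per
#' row); the matrix path is vectorised across spectra.
#'
#' @param A Absorbance vector or matrix.
#' @param order Derivative order, 1 or 2.
#' @param spec A [preproc_spec()] supplying `sg_window` and `sg_polyorder`.
#' @return Derivative of the same shape as `A`.
#' @export
sg_derivative <- function(A, order, spec = preproc_spec()) {
  if (!order %in% c(1L, 2L)) abort("`order` must be 1 or 2")
  vec <- is.null(dim(A))
  if (vec) A <- matrix(A, nrow = 1L)
  len <- ncol(A)
  w <- spec$sg_window
  if (len < w) abort("spectrum shorter than the Savitzky-Golay window")
  Fm <- unclass(signal::sgolay(p = spec$sg_polyorder, n = w, m = order))
  k <- floor(w / 2)
  cc <- Fm[k + 1, ]
  out <- matrix(0, nrow(A), len)
  mid <- (k + 1L):(len - k)
  for (t in seq_len(w)) { # interior: shifted-column accumulation
    out[, mid] <- out[, mid] + cc[t] * A[, mid + t - (k + 1L), drop = FALSE]
  }
  out[, 1:k] <- A[, 1:w, drop = FALSE] %*% t(Fm[1:k, , drop = FALSE])
  out[, (len - k + 1):len] <- A[, (len - w + 1):len, drop = FALSE] %*%
    t(Fm[(k + 2):w, , drop = FALSE])
  if (vec) out[1, ] else out
}

#' Trim spectral edges
#'
#' Drops `trim_points` values from each end of a spectrum (vector) or from the
#' columns of a spectra matrix.
#'
#' @param v Vector or matrix.
#' @param trim_points Points removed per edge.
#' @return Trimmed vector/matrix.
#' @export
#' @examples
#' length(trim_edges(seq_len(1024), 75))
trim_edges <- function(v, trim_points) {
  n <- if (is.null(dim(v))) length(v) else ncol(v)
  if (n <= 2L * trim_points) abort("nothing left after trimming")
  keep <- (trim_points + 1L):(n - trim_points)
  if (is.null(dim(v))) v[keep] else v[, keep, drop = FALSE]
}

#' Standard Normal Variate correction
#'
#' Centers and scales each spectrum to mean 0 and (population) standard
#' deviation 1, computed over spectral features only.
#'
#' @param v Spectrum vector or spectra matrix (one spectrum per row).
#' @return Same shape as `v`.
#' @export
#' @examples
#' snv(c(1, 2, 3))
snv <- function(v) {
  vec <- is.null(dim(v))
  if (vec) v <- matrix(v, nrow = 1L)
  m <- rowMeans(v)
  s <- sqrt(rowMeans((v - m)^2))
  if (any(s <= 0)) abort("constant spectrum: SNV undefined (zero variance)")
  out <- (v - m) / s
  if (vec) out[1, ] else out
}

#' Build one preprocessed data type
#'
#' Runs the fixed pipeline (see file header) on a population tibble and
#' returns a `feature_matrix`: the X-block (trimmed spectral features, plus
#' temperature and size when `spec$augmented`), the Y-block (SSC in degrees
#' Brix) and sample metadata.
#'
#' @param samples Population tibble (from [generate_population()] or
#'   [read_population_csv()]).
#' @param spec A [preproc_spec()].
#' @return A `feature_matrix` object.
#' @export
#' @examples
#' pop <- generate_population(generator_config(n_fruits = 15, seed = 1))
#' fm <- build_data_type(pop, preproc_spec("absorbance"))
#' dim(fm$X)
build_data_type <- function(samples, spec) {
  stopifnot(inherits(spec, "preproc_spec"), nrow(samples) > 0)
  spec_cols <- grep("^r_", names(samples), value = TRUE)
  if (length(spec_cols) == 0) abort("no reflectance columns (r_*) in `samples`")
  wl <- as.numeric(sub("^r_", "", spec_cols))
  R <- as.matrix(samples[, spec_cols])
  X <- reflectance_to_absorbance(R)
  if (spec$base == "deriv1") X <- sg_derivative(X, 1L, spec)
  if (spec$base == "deriv2") X <- sg_derivative(X, 2L, spec)
  X <- trim_edges(X, spec$trim_points)
  wl <- trim_edges(wl, spec$trim_points)
  if (spec$spectral_range == "noChl") {
    keep <- wl >= spec$chl_cutoff_nm
    if (!any(keep)) abort("chl_cutoff_nm removes the whole spectrum")
    X <- X[, keep, drop = FALSE]
    wl <- wl[keep]
  }
  if (spec$snv) X <- snv(X)
  labels <- sprintf("%07.2f", wl)
  is_spectral <- rep(TRUE, ncol(X))
  if (spec$augmented) {
    X <- cbind(X, samples$temperature_C, samples$diameter_mm)
    labels <- c(labels, "temperature", "size")
    is_spectral <- c(is_spectral, FALSE, FALSE)
    wl <- c(wl, NA_real_, NA_real_)
  }
  colnames(X) <- labels
  new_feature_matrix(
    X = X, y = samples$ssc_brix, feature_labels = labels,
    wavelengths = wl, is_spectral = is_spectral,
    meta = samples[, intersect(
      c("fruit_id", "side", "subset", "acquisition_index",
        "temperature_C", "diameter_mm"), names(samples))],
    spec = spec
  )
}

#' @noRd
new_feature_matrix <- function(X, y, feature_labels, wavelengths, is_spectral,
                               meta, spec, scaling = NULL) {
  if (anyNA(X) || anyNA(y)) abort("feature matrix must not contain NA")
  stopifnot(length(feature_labels) == ncol(X), length(y) == nrow(X))
  structure(
    list(X = X, y = y, feature_labels = feature_labels,
         wavelengths = wavelengths, is_spectral = is_spectral,
         meta = as_tibble(meta), spec = spec, scaling = scaling),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s (%s): %d samples x %d features (%d spectral)\n",
              data_type_name(x$spec), x$spec$spectral_range,
              nrow(x$X), ncol(x$X), sum(x$is_spectral)))
  invisible(x)
}

#' Subset a feature matrix by sample rows
#' @param fm A `feature_matrix`.
#' @param rows Integer or logical row index.
#' @return A `feature_matrix` with the selected samples.
#' @export
fm_rows <- function(fm, rows) {
  new_feature_matrix(fm$X[rows, , drop = FALSE], fm$y[rows],
                     fm$feature_labels, fm$wavelengths, fm$is_spectral,
                     fm$meta[rows, , drop = FALSE], fm$spec, fm$scaling)
}

#' Thin spectral features (desk-scale runs)
#'
#' Keeps every `step`-th spectral column (after full-resolution
#' preprocessing), all augmented columns retained. Used to scale benchmark
#' problem sizes down without changing preprocessing semantics.
#'
#' @param fm A `feature_matrix`.
#' @param step Keep every `step`-th spectral feature.
#' @return A thinned `feature_matrix`.
#' @export
thin_features <- function(fm, step) {
  if (step <= 1L) return(fm)
  sp <- which(fm$is_spectral)
  keep <- sort(c(sp[seq(1L, length(sp), by = step)], which(!fm$is_spectral)))
  new_feature_matrix(fm$X[, keep, drop = FALSE], fm$y,
                     fm$feature_labels[keep], fm$wavelengths[keep],
                     fm$is_spectral[keep], fm$meta, fm$spec, fm$scaling)
}

#' Tidy a feature matrix into a long tibble
#'
#' @param x A `feature_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per (sample, feature).
#' @method tidy feature_matrix
#' @export
tidy.feature_matrix <- function(x, ...) {
  tibble(
    sample = rep(seq_len(nrow(x$X)), times = ncol(x$X)),
    feature = rep(x$feature_labels, each = nrow(x$X)),
    wavelength_nm = rep(x$wavelengths, each = nrow(x$X)),
    value = as.vector(x$X),
    ssc_brix = rep(x$y, times = ncol(x$X))
  )
}

#' Scale a feature matrix for the support-vector engine
#'
#' Spectral features get the per-base-variant scalar (absorbance / 10, first
#' derivative x 100, second derivative x 1000); appended temperature and size
#' are centered on *calibration* means and divided by 100. SNV variants are
#' already on a unit scale whatever the base transform, so they take the
#' absorbance rule (/ 10) instead of the derivative multipliers. Calibration
#' centering constants are stored in the result and must be passed back via
#' `stats` when scaling validation samples.
#'
#' @param fm A `feature_matrix`.
#' @param stats Scaling statistics from a previous (calibration) call, or
#'   `NULL` to compute them from `fm`.
#' @return A `feature_matrix` with scaled `X` and a `scaling` element
#'   (`base_factor`, `aug_center`).
#' @export
scale_for_svm <- function(fm, stats = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  factor <- if (fm$spec$snv) 0.1 else
    switch(fm$spec$base,
           absorbance = 0.1, deriv1 = 100, deriv2 = 1000,
           abort("unknown base variant"))
  X <- fm$X
  X[, fm$is_spectral] <- X[, fm$is_spectral] * factor
  aug <- which(!fm$is_spectral)
  aug_center <- NULL
  if (length(aug) > 0) {
    aug_center <- if (is.null(stats)) colMeans(fm$X[, aug, drop = FALSE]) else
      stats$aug_center
    X[, aug] <- sweep(fm$X[, aug, drop = FALSE], 2, aug_center) / 100
  }
  new_feature_matrix(X, fm$y, fm$feature_labels, fm$wavelengths,
                     fm$is_spectral, fm$meta, fm$spec,
                     scaling = list(base_factor = factor,
                                    aug_center = aug_center))
}
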