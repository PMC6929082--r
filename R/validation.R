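# Validation strategies and the metric suite.
#
# Internal validation (IV): seeded shuffle, 80/20 calibration/validation.
# External validation (EV): calibrate on four chronological subsets, predict
# the held-out fifth, for all five rotations. Splits operate at fruit level by
# default: the two sides of one pear are near-duplicates, and letting them
# straddle the partition inflates internal-validation optimism. A flag
# restores literal sample-level splitting.

#' @noRd
new_split_plan <- function(strategy, cal, val, rotation = NA_character_,
                           seed = NA_integer_) {
  structure(list(strategy = strategy, calibration_indices = cal,
                 validation_indices = val, rotation_label = rotation,
                 seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s%s: %d calibration / %d validation samples\n",
              x$strategy,
              if (!is.na(x$rotation_label)) paste0(" (holdout ", x$rotation_label, ")") else "",
              length(x$calibration_indices), length(x$validation_indices)))
  invisible(x)
}

#' Internal (random 80/20) split
#'
#' @param samples Population tibble (needs `fruit_id` unless
#'   `fruit_level = FALSE`).
#' @param fraction Calibration fraction (default 0.8).
#' @param seed Shuffle seed.
#' @param fruit_level Keep both sides of a fruit in the same partition
#'   (default `TRUE`).
#' @param strategy Label stored in the plan (`"IV_big"` or `"IV_small"`).
#' @return A `split_plan` with row indices into `samples`.
#' @export
make_internal_split <- function(samples, fraction = 0.8, seed = 1L,
                                fruit_level = TRUE, strategy = "IV_big") {
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1)")
  n <- nrow(samples)
  if (fruit_level) {
    if (dplyr::n_distinct(samples$fruit_id) < 10) {
      abort("need at least 10 fruits for a split")
    }
    fruits <- unique(samples$fruit_id)
    shuffled <- with_seed(seed, sample(fruits))
    n_cal <- round(fraction * length(fruits))
    cal_fruits <- shuffled[seq_len(n_cal)]
    cal <- which(samples$fruit_id %in% cal_fruits)
    val <- which(!samples$fruit_id %in% cal_fruits)
  } else {
    shuffled <- with_seed(seed, sample.int(n))
    n_cal <- round(fraction * n)
    cal <- sort(shuffled[seq_len(n_cal)])
    val <- sort(shuffled[-seq_len(n_cal)])
  }
  new_split_plan(strategy, cal, val, seed = seed)
}

#' External (chronological) validation rotations
#'
#' One plan per held-out subset label: calibration = the union of the other
#' four subsets, validation = the held-out one. No shuffling; the
#' chronological structure is the point.
#'
#' @param samples Population tibble with a `subset` column covering all of
#'   A-E.
#' @return List of five `split_plan`s (holdouts A, B, C, D, E).
#' @export
make_external_rotations <- function(samples) {
  labels <- LETTERS[1:5]
  missing <- setdiff(labels, unique(samples$subset))
  if (length(missing) > 0) {
    abort(sprintf("missing subset label(s): %s", paste(missing, collapse = ", ")))
  }
  purrr::map(labels, function(lab) {
    val <- which(samples$subset == lab)
    new_split_plan("EV", which(samples$subset != lab), val, rotation = lab)
  })
}

#' Prediction metrics for one (data type, model, split) cell
#'
#' Computes RMSEP, the squared Pearson correlation between observed and
#' predicted (headline R2; `r2_1sse` = 1 - SSE/SST is also reported), the
#' coefficient of variation `100 * RMSEP / mean(y_val)`, the standard
#' deviation ratio `SDR = sd(y_val) / RMSEP` (population sd) and the
#' Prediction Gain `PG = rms(y_val - mean(y_cal)) / RMSEP`, i.e. the RMSEP a
#' zero-order model predicting the calibration mean would incur, divided by
#' the model's RMSEP. PG equals SDR exactly when calibration and validation
#' means coincide, and exceeds it when the model bridges differing means.
#'
#' @param y_cal Calibration SSC values (only their mean enters PG).
#' @param y_val Observed validation SSC.
#' @param y_pred Predicted validation SSC.
#' @param rmsec,rmsecv Carried through into the report (optional).
#' @return A one-row tibble: `rmsec`, `rmsecv`, `rmsep`, `r2`, `r2_1sse`,
#'   `cv_percent`, `sdr`, `pg`, `n_cal`, `n_val`, `degenerate` (TRUE when
#'   `rmsep == 0` and PG/SDR are infinite).
#' @export
#' @examples
#' compute_metrics(y_cal = c(12, 14), y_val = c(12, 14), y_pred = c(12.5, 13.5))
compute_metrics <- function(y_cal, y_val, y_pred,
                            rmsec = NA_real_, rmsecv = NA_real_) {
  if (length(y_val) != length(y_pred) || length(y_val) < 2) {
    abort("`y_val` and `y_pred` must have equal length > 1")
  }
  rmsep <- rms(y_val - y_pred)
  degenerate <- rmsep == 0
  if (degenerate) {
    warn("RMSEP is exactly 0: PG and SDR are infinite")
  }
  r2 <- if (sd(y_pred) == 0 || sd(y_val) == 0) NA_real_ else
    cor(y_val, y_pred)^2
  tibble(
    rmsec = rmsec, rmsecv = rmsecv, rmsep = rmsep,
    r2 = r2,
    r2_1sse = 1 - sum((y_val - y_pred)^2) / sum((y_val - mean(y_val))^2),
    cv_percent = 100 * rmsep / mean(y_val),
    sdr = sd_pop(y_val) / rmsep,
    pg = rms(y_val - mean(y_cal)) / rmsep,
    n_cal = length(y_cal), n_val = length(y_val),
    degenerate = degenerate
  )
}

#' Aggregate the five external-validation rotations
#'
#' Arithmetic mean of every metric across the five rotations, plus the
#' population standard deviation of RMSEP (the error-bar summary).
#'
#' @param reports A tibble of exactly five metric rows (one per rotation), or
#'   a list of such one-row tibbles.
#' @return A one-row tibble like [compute_metrics()] output with an extra
#'   `rmsep_sd` column; counts are summed.
#' @export
aggregate_ev <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports)) {
    reports <- dplyr::bind_rows(reports)
  }
  if (nrow(reports) != 5) abort("external validation needs exactly 5 rotations")
  means <- dplyr::summarise(reports, dplyr::across(
    c("rmsec", "rmsecv", "rmsep", "r2", "r2_1sse", "cv_percent", "sdr", "pg"),
    mean))
  dplyr::bind_cols(
    means,
    tibble(rmsep_sd = sd_pop(reports$rmsep),
           n_cal = sum(reports$n_cal), n_val = sum(reports$n_val),
           degenerate = any(reports$degenerate))
  )
}
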