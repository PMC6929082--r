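# Full factorial benchmark: preprocessing grid x calibration engines x
# validation strategies (with the external strategy's five rotations).
#
# Per cell: build the data type -> wrapper feature selection on the
# calibration partition only -> apply the mask to calibration and validation
# -> fit the engine -> predict -> metrics. Every seed is derived
# deterministically from the master seed, so identical configurations give
# bit-identical result tables. Per-cell failures are recorded with a reason
# and the run continues (mirroring the deliberate skip of MLR where features
# outnumber samples).

#' Benchmark run configuration
#'
#' @param generator A [generator_config()]; its seed is overridden by a seed
#'   derived from `master_seed`.
#' @param specs List of [preproc_spec()]s (default: the full 24-recipe grid).
#' @param models Engines to run, subset of `c("PLS", "MLR", "SVM", "MLP")`.
#' @param strategies Subset of `c("IV_big", "IV_small", "EV")`.
#' @param master_seed Single seed every other seed is derived from.
#' @param feature_selection Run the PLS wrapper selection per calibration
#'   partition (default `TRUE`).
#' @param max_lv Maximum latent variables for selection / PLS (default 25).
#' @param fs_recompute_ranking Full wrapper (re-rank after each removal) or
#'   fixed per-#LV ranking (cheaper); default `TRUE`.
#' @param feature_step Keep every `feature_step`-th spectral feature after
#'   preprocessing (desk-scale runs; 1 = full resolution).
#' @param mlp_repeats Networks averaged by the MLP engine (default 3 at CI
#'   scale; 10 reproduces the full protocol).
#' @param svm_candidates Randomized-search candidates per coordinate pass.
#' @param sample_level_splits Literal sample-level internal splits instead of
#'   fruit-level (fidelity flag; default `FALSE`).
#' @param iv_fraction Internal-validation calibration fraction (default 0.8).
#' @param small_n_fruits Fruits in the uniform "Small" set (default 150, i.e.
#'   300 samples).
#' @param min_diameter Small-fruit filter threshold in mm.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(generator = generator_config(),
                             specs = preproc_grid(),
                             models = c("PLS", "MLR", "SVM", "MLP"),
                             strategies = c("IV_big", "IV_small", "EV"),
                             master_seed = 1L,
                             feature_selection = TRUE,
                             max_lv = 25L,
                             fs_recompute_ranking = TRUE,
                             feature_step = 1L,
                             mlp_repeats = 3L,
                             svm_candidates = 30L,
                             sample_level_splits = FALSE,
                             iv_fraction = 0.8,
                             small_n_fruits = 150L,
                             min_diameter = 42) {
  models <- match.arg(models, c("PLS", "MLR", "SVM", "MLP"),
                      several.ok = TRUE)
  strategies <- match.arg(strategies, c("IV_big", "IV_small", "EV"),
                          several.ok = TRUE)
  if (length(specs) == 0) abort("need at least one preprocessing spec")
  structure(list(generator = generator, specs = specs, models = models,
                 strategies = strategies, master_seed = as.integer(master_seed),
                 feature_selection = isTRUE(feature_selection),
                 max_lv = as.integer(max_lv),
                 fs_recompute_ranking = isTRUE(fs_recompute_ranking),
                 feature_step = as.integer(feature_step),
                 mlp_repeats = as.integer(mlp_repeats),
                 svm_candidates = as.integer(svm_candidates),
                 sample_level_splits = isTRUE(sample_level_splits),
                 iv_fraction = iv_fraction,
                 small_n_fruits = as.integer(small_n_fruits),
                 min_diameter = min_diameter),
            class = "benchmark_config")
}

#' Extract the uniform "Small" subset of a population
#'
#' Emulates a one-week acquisition of uniform fruit: ambient temperatures
#' (15-28 C) and mid-range diameters (52-68 mm), first `n_fruits` qualifying
#' fruits in acquisition order.
#'
#' @param samples Population tibble.
#' @param n_fruits Number of fruits to keep (default 150 -> 300 samples).
#' @return Population tibble restricted to the Small set.
#' @export
make_small_set <- function(samples, n_fruits = 150L) {
  per_fruit <- dplyr::summarise(
    dplyr::group_by(samples, .data$fruit_id),
    temperature_C = .data$temperature_C[1],
    diameter_mm = .data$diameter_mm[1],
    first_idx = min(.data$acquisition_index),
    .groups = "drop"
  )
  ok <- dplyr::filter(per_fruit,
                      .data$temperature_C >= 15, .data$temperature_C <= 28,
                      .data$diameter_mm >= 52, .data$diameter_mm <= 68)
  ok <- dplyr::arrange(ok, .data$first_idx)
  if (nrow(ok) < 25) abort("not enough uniform fruits for a Small set")
  keep <- head(ok$fruit_id, n_fruits)
  dplyr::filter(samples, .data$fruit_id %in% keep)
}

#' Choose the PLS component count without wavelength selection
#' @noRd
choose_n_lv <- function(X, y, max_lv, cv_seed, cv_folds = 5L) {
  folds <- make_folds(nrow(X), cv_folds, cv_seed)
  max_lv <- min(max_lv, ncol(X),
                nrow(X) - ceiling(nrow(X) / cv_folds) - 1L)
  r <- pls_cv_rmse(X, y, max_lv, folds)
  list(n_lv = which.min(r), rmsecv = min(r))
}

#' Fit one engine on one prepared cell
#' @noRd
fit_cell_model <- function(model, fm_cal, fm_val, n_lv, seed, config) {
  if (model == "PLS") {
    m <- fit_pls(fm_cal, n_lv = n_lv, cv_folds = 10L,
                 cv_seed = derive_seed(seed, "rmsec"))
    list(model = m, pred = predict(m, fm_val))
  } else if (model == "MLR") {
    m <- fit_mlr(fm_cal, cv_folds = 10L, cv_seed = derive_seed(seed, "rmsec"))
    list(model = m, pred = predict(m, fm_val))
  } else if (model == "SVM") {
    cal_s <- scale_for_svm(fm_cal)
    val_s <- scale_for_svm(fm_val, stats = cal_s$scaling)
    m <- svm_optimize(cal_s, n_candidates = config$svm_candidates,
                      seed = derive_seed(seed, "svm"))
    list(model = m, pred = predict(m, val_s))
  } else if (model == "MLP") {
    cfg <- mlp_config(ncol(fm_cal$X), n_repeats = config$mlp_repeats)
    m <- fit_mlp(fm_cal, config = cfg, seed = derive_seed(seed, "mlp"))
    list(model = m, pred = predict(m, fm_val$X))
  } else {
    abort(sprintf("unknown model '%s'", model))
  }
}

#' Run the calibration benchmark
#'
#' @param config A [benchmark_config()].
#' @param quiet Suppress per-cell progress messages.
#' @return A `benchmark_result`: `cells` (one tibble row per
#'   (data type, range, model, strategy, rotation) with metrics and
#'   feature-selection bookkeeping), `ev_summary` (EV rotations aggregated),
#'   `best_table` (lowest-RMSEP data type per model/strategy/range) and the
#'   config.
#' @export
run_benchmark <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "benchmark_config"))
  gen <- config$generator
  gen$seed <- derive_seed(config$master_seed, "data")
  pop <- apply_small_fruit_filter(generate_population(gen),
                                  config$min_diameter)
  datasets <- list()
  if (any(c("IV_big", "EV") %in% config$strategies)) datasets$big <- pop
  if ("IV_small" %in% config$strategies) {
    datasets$small <- make_small_set(pop, config$small_n_fruits)
  }

  plans_for <- function(strategy) {
    if (strategy == "EV") {
      make_external_rotations(datasets$big)
    } else if (strategy == "IV_big") {
      list(make_internal_split(
        datasets$big, config$iv_fraction,
        seed = derive_seed(config$master_seed, "split-IV_big"),
        fruit_level = !config$sample_level_splits, strategy = "IV_big"))
    } else {
      list(make_internal_split(
        datasets$small, config$iv_fraction,
        seed = derive_seed(config$master_seed, "split-IV_small"),
        fruit_level = !config$sample_level_splits, strategy = "IV_small"))
    }
  }

  fm_cache <- new.env(parent = emptyenv())
  get_fm <- function(ds_name, spec) {
    key <- paste(ds_name, data_type_name(spec), spec$spectral_range, sep = "|")
    if (is.null(fm_cache[[key]])) {
      fm_cache[[key]] <- thin_features(
        build_data_type(datasets[[ds_name]], spec), config$feature_step)
    }
    fm_cache[[key]]
  }

  rows <- list()
  for (strategy in config$strategies) {
    ds_name <- if (strategy == "IV_small") "small" else "big"
    plans <- plans_for(strategy)
    for (spec in config$specs) {
      dtype <- data_type_name(spec)
      fm <- get_fm(ds_name, spec)
      for (plan in plans) {
        rot <- plan$rotation_label
        cell_tag <- paste(strategy, rot, dtype, spec$spectral_range, sep = "|")
        fm_cal <- fm_rows(fm, plan$calibration_indices)
        fm_val <- fm_rows(fm, plan$validation_indices)
        fs_seed <- derive_seed(config$master_seed, paste0("fs|", cell_tag))
        if (config$feature_selection) {
          fsr <- wrapper_select(
            fm_cal$X, fm_cal$y, max_lv = config$max_lv, cv_folds = 5L,
            cv_seed = fs_seed, is_spectral = fm_cal$is_spectral,
            recompute_ranking = config$fs_recompute_ranking)
          fm_cal_m <- apply_selection(fm_cal, fsr)
          fm_val_m <- apply_selection(fm_val, fsr)
          n_lv <- fsr$n_lv
          rmsecv <- fsr$rmsecv
          n_disc <- fsr$n_discarded
        } else {
          sel <- choose_n_lv(fm_cal$X, fm_cal$y, config$max_lv, fs_seed)
          fm_cal_m <- fm_cal; fm_val_m <- fm_val
          n_lv <- sel$n_lv; rmsecv <- sel$rmsecv; n_disc <- 0L
        }
        for (model in config$models) {
          if (!quiet) message(sprintf("[%s] %s %s", model, cell_tag, ""))
          seed_m <- derive_seed(config$master_seed,
                                paste0("model|", model, "|", cell_tag))
          res <- tryCatch(
            fit_cell_model(model, fm_cal_m, fm_val_m, n_lv, seed_m, config),
            error = function(e) e
          )
          base_row <- tibble(
            data_type = dtype, spectral_range = spec$spectral_range,
            model = model, strategy = strategy,
            rotation = rot %||% NA_character_,
            n_features = ncol(fm_cal_m$X),
            fs_n_discarded = n_disc, fs_n_lv = n_lv
          )
          if (inherits(res, "error")) {
            rows[[length(rows) + 1L]] <- dplyr::bind_cols(
              base_row,
              tibble(status = "skipped", reason = conditionMessage(res)))
          } else {
            met <- compute_metrics(fm_cal_m$y, fm_val_m$y, res$pred,
                                   rmsec = res$model$rmsec, rmsecv = rmsecv)
            hp <- res$model$hyperparams
            rows[[length(rows) + 1L]] <- dplyr::bind_cols(
              base_row, tibble(status = "ok", reason = NA_character_), met,
              tibble(svm_C = hp$C %||% NA_real_,
                     svm_gamma = hp$gamma %||% NA_real_,
                     svm_epsilon = hp$epsilon %||% NA_real_))
          }
        }
      }
    }
  }
  cells <- dplyr::bind_rows(rows)
  new_benchmark_result(cells, config)
}

#' @noRd
new_benchmark_result <- function(cells, config) {
  ok <- dplyr::filter(cells, .data$status == "ok")
  ev_summary <- NULL
  if (any(ok$strategy == "EV")) {
    ev_summary <- dplyr::group_by(
      dplyr::filter(ok, .data$strategy == "EV"),
      .data$data_type, .data$spectral_range, .data$model) |>
      dplyr::group_modify(function(df, key) {
        if (nrow(df) == 5) aggregate_ev(df) else
          tibble(rmsep = NA_real_)
      }) |>
      dplyr::ungroup()
    ev_summary <- dplyr::filter(ev_summary, is.finite(.data$rmsep))
  }
  iv_best <- dplyr::filter(ok, .data$strategy != "EV") |>
    dplyr::group_by(.data$model, .data$strategy, .data$spectral_range) |>
    dplyr::slice_min(.data$rmsep, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("model", "strategy", "spectral_range", "data_type",
                  "rmsec", "rmsep", "r2", "cv_percent", "pg")
  ev_best <- NULL
  if (!is.null(ev_summary) && nrow(ev_summary) > 0) {
    ev_best <- dplyr::group_by(ev_summary, .data$model, .data$spectral_range) |>
      dplyr::slice_min(.data$rmsep, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::mutate(strategy = "EV*") |>
      dplyr::select("model", "strategy", "spectral_range", "data_type",
                    "rmsec", "rmsep", "r2", "cv_percent", "pg")
  }
  best_table <- dplyr::bind_rows(ev_best, iv_best)
  if (nrow(best_table) > 0) {
    best_table <- dplyr::arrange(
      best_table, .data$model,
      match(.data$spectral_range, c("full", "noChl")),
      match(.data$strategy, c("EV*", "IV_big", "IV_small")))
  }
  structure(list(cells = cells, ev_summary = ev_summary,
                 best_table = best_table, config = config),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d cells (%d ok, %d skipped)\n",
              nrow(x$cells), sum(x$cells$status == "ok"),
              sum(x$cells$status == "skipped")))
  if (nrow(x$best_table) > 0) {
    cat("best data types (lowest RMSEP):\n")
    print(as.data.frame(x$best_table), digits = 3)
  }
  invisible(x)
}

#' All benchmark cells as a tidy tibble
#' @param x A `benchmark_result`.
#' @param ... Unused.
#' @method tidy benchmark_result
#' @export
tidy.benchmark_result <- function(x, ...) x$cells

#' One-row benchmark summary
#' @param x A `benchmark_result`.
#' @param ... Unused.
#' @method glance benchmark_result
#' @export
glance.benchmark_result <- function(x, ...) {
  ok <- dplyr::filter(x$cells, .data$status == "ok")
  tibble(n_cells = nrow(x$cells), n_ok = nrow(ok),
         n_skipped = sum(x$cells$status == "skipped"),
         best_rmsep = if (nrow(ok) > 0) min(ok$rmsep) else NA_real_,
         master_seed = x$config$master_seed)
}

#' Best-per-cell summary tables
#'
#' One tibble row per (model, strategy, range) in the canonical order
#' (EV* full, Big full, Small full, EV* noChl, Big noChl, Small noChl within
#' each model) with the winning data type and its metrics. Byte-stable
#' ordering for CSV export.
#'
#' @param result A `benchmark_result`.
#' @return A tibble.
#' @export
summarize_best <- function(result) {
  stopifnot(inherits(result, "benchmark_result"))
  if (nrow(result$best_table) == 0) abort("empty benchmark result")
  dplyr::arrange(
    result$best_table, .data$model,
    match(.data$spectral_range, c("full", "noChl")),
    match(.data$strategy, c("EV*", "IV_big", "IV_small")))
}

#' Paired RMSEP with vs without wavelength selection
#'
#' Runs every cell of the configuration twice -- once with the PLS wrapper
#' selection, once without (full wavelength set, #LV chosen by the same
#' seeded cross-validation) -- on identical splits, and returns the paired
#' RMSEP differences (negative `delta_rmsep` = selection wins).
#'
#' @param config A [benchmark_config()]; its `feature_selection` flag is
#'   overridden on each arm.
#' @return A tibble with one row per cell: both RMSEPs and their difference.
#' @export
compare_with_without_selection <- function(config) {
  cfg_on <- config; cfg_on$feature_selection <- TRUE
  cfg_off <- config; cfg_off$feature_selection <- FALSE
  on <- run_benchmark(cfg_on)$cells
  off <- run_benchmark(cfg_off)$cells
  keys <- c("data_type", "spectral_range", "model", "strategy", "rotation")
  dplyr::inner_join(
    dplyr::select(dplyr::filter(on, .data$status == "ok"),
                  dplyr::all_of(keys), rmsep_selected = "rmsep",
                  fs_n_discarded = "fs_n_discarded"),
    dplyr::select(dplyr::filter(off, .data$status == "ok"),
                  dplyr::all_of(keys), rmsep_full = "rmsep"),
    by = keys
  ) |>
    dplyr::mutate(delta_rmsep = .data$rmsep_selected - .data$rmsep_full)
}

#' Plot benchmark RMSEP by data type, engine and strategy
#'
#' @param object A `benchmark_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot benchmark_result
#' @export
autoplot.benchmark_result <- function(object, ...) {
  ok <- dplyr::filter(object$cells, .data$status == "ok")
  ggplot(ok, aes(x = .data$data_type, y = .data$rmsep,
                 colour = .data$model, shape = .data$spectral_range)) +
    geom_point(position = position_dodge(width = 0.5), size = 2) +
    facet_wrap(~ .data$strategy, scales = "free_y") +
    labs(x = NULL, y = "RMSEP (°Brix)", colour = "engine", shape = "range") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot a handful of spectra from a population
#'
#' @param samples Population tibble.
#' @param n Number of spectra to draw (default 30, first `n` rows).
#' @param as Plot reflectance or absorbance.
#' @return A ggplot.
#' @export
plot_spectra <- function(samples, n = 30, as = c("reflectance", "absorbance")) {
  as <- match.arg(as)
  spec_cols <- grep("^r_", names(samples), value = TRUE)
  wl <- as.numeric(sub("^r_", "", spec_cols))
  n <- min(n, nrow(samples))
  M <- as.matrix(samples[seq_len(n), spec_cols])
  if (as == "absorbance") M <- reflectance_to_absorbance(M)
  df <- tibble(
    sample = rep(seq_len(n), times = length(wl)),
    wavelength_nm = rep(wl, each = n),
    value = as.vector(M),
    ssc = rep(samples$ssc_brix[seq_len(n)], times = length(wl))
  )
  ggplot(df, aes(x = .data$wavelength_nm, y = .data$value,
                 group = .data$sample, colour = .data$ssc)) +
    geom_line(alpha = 0.6) +
    scale_colour_viridis_c(name = "SSC (°Brix)") +
    labs(x = "wavelength (nm)", y = as) +
    theme_minimal()
}
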