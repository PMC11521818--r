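#' Regression evaluation statistics
#'
#' Computes the five evaluation statistics used throughout the pipeline:
#' \itemize{
#'   \item R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
#'   \item RMSE = sqrt(mean((y - yhat)^2)), ug/g
#'   \item MAE = mean(|yhat - y|), ug/g
#'   \item MBD = mean(y - yhat), ug/g (positive = under-prediction)
#'   \item MSPE = mean((y - yhat)^2), (ug/g)^2 (= RMSE^2)
#' }
#'
#' @param y_true measured chlorophyll vector.
#' @param y_pred estimated chlorophyll vector, same length (>= 2 for R2).
#' @return An object of class \code{metrics_bundle}: list with \code{r2},
#'   \code{rmse}, \code{mae}, \code{mbd}, \code{mspe}. When \code{y_true}
#'   has zero variance R2 is NA with a warning; the other statistics are
#'   still returned.
#' @export
#' @examples
#' metrics(c(1, 2, 3), c(1, 2, 4))
metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    chl_stop("chlorospec_input_error", "y_true and y_pred must match in length")
  if (length(y_true) < 2)
    chl_stop("chlorospec_input_error", "need at least 2 observations")
  err <- y_true - y_pred
  mspe <- mean(err^2)
  tss <- sum((y_true - mean(y_true))^2)
  r2 <- if (tss < 1e-24) {
    warning("zero variance in y_true; R2 undefined", call. = FALSE)
    NA_real_
  } else 1 - sum(err^2) / tss
  structure(list(r2 = r2, rmse = sqrt(mspe), mae = mean(abs(err)),
                 mbd = mean(err), mspe = mspe),
            class = "metrics_bundle")
}

#' @export
print.metrics_bundle <- function(x, ...) {
  cat(sprintf("R2 %.3f | RMSE %.3f | MAE %.3f | MBD %.3f | MSPE %.3f\n",
              x$r2, x$rmse, x$mae, x$mbd, x$mspe))
  invisible(x)
}

#' @export
as.data.frame.metrics_bundle <- function(x, ...) {
  data.frame(r2 = x$r2, rmse = x$rmse, mae = x$mae, mbd = x$mbd,
             mspe = x$mspe)
}

split_indices <- function(x) {
  n <- if (inherits(x, "spectra_set")) length(x$records)
       else if (is.data.frame(x) || is.matrix(x)) nrow(x)
       else length(x)
  n
}

take_subset <- function(x, idx) {
  if (inherits(x, "spectra_set")) spectra_set(x$records[idx])
  else if (inherits(x, "feature_table"))
    feature_table(as.data.frame(x)[idx, , drop = FALSE],
                  attr(x, "feature_names"))
  else if (is.data.frame(x) || is.matrix(x)) x[idx, , drop = FALSE]
  else x[idx]
}

#' Every-third-record train/validation split
#'
#' Records at ordinal positions 3, 6, 9, ... form the validation set; the
#' rest train. Order is preserved within each part; the parts are disjoint
#' and exhaustive. 540 ordered records yield 360 training and 180
#' validation records.
#'
#' @param x an ordered dataset: [spectra_set()], [feature_table()],
#'   data.frame, matrix or vector with >= 3 records.
#' @return List with \code{training}, \code{validation} and the index
#'   vectors \code{training_idx}, \code{validation_idx}.
#' @export
split_every_third <- function(x) {
  n <- split_indices(x)
  if (n < 3)
    chl_stop("chlorospec_split_error", "need at least 3 records")
  val <- seq(3, n, by = 3)
  tr <- setdiff(seq_len(n), val)
  list(training = take_subset(x, tr), validation = take_subset(x, val),
       training_idx = tr, validation_idx = val)
}

#' Seeded random train/validation split
#'
#' Shuffles record order with the given seed, then assigns
#' \code{floor(n * fraction)} records (at least 1, and leaving at least one
#' training record) to validation.
#'
#' @param x dataset as in [split_every_third()].
#' @param fraction validation share in (0, 1).
#' @param seed RNG seed.
#' @return List as in [split_every_third()].
#' @export
split_random <- function(x, fraction = 1 / 3, seed = 1) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    chl_stop("chlorospec_config_error", "fraction must be in (0, 1)")
  n <- split_indices(x)
  n_val <- min(max(1L, floor(n * fraction)), n - 1L)
  perm <- with_seed(seed, sample.int(n))
  val <- perm[seq_len(n_val)]
  tr <- perm[(n_val + 1):n]
  list(training = take_subset(x, tr), validation = take_subset(x, val),
       training_idx = tr, validation_idx = val)
}

#' Simple linear calibration of one index against chlorophyll
#'
#' Least-squares line of chlorophyll on a single index value, reporting the
#' signed Pearson correlation alongside slope and intercept.
#'
#' @param index_values index value per sample.
#' @param chlorophyll chlorophyll labels, same length (n >= 3).
#' @return List with \code{slope}, \code{intercept}, \code{r} and the
#'   fitted values.
#' @export
simple_linear_calibration <- function(index_values, chlorophyll) {
  if (length(index_values) != length(chlorophyll) || length(index_values) < 3)
    chl_stop("chlorospec_input_error", "need matched vectors of length >= 3")
  if (stats::sd(index_values) < 1e-12)
    chl_stop("chlorospec_fit_error", "zero variance in index values")
  fit <- stats::lm(chlorophyll ~ index_values)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = stats::cor(index_values, chlorophyll),
       fitted = unname(stats::fitted(fit)))
}

default_pipeline_config <- function() {
  list(version = "1",
       seed = 42L,
       generator = list(),          # generator_config() overrides
       spectra_csv = NULL,          # or a CSV path
       split = list(scheme = "random", fraction = 1 / 3),
       models = model_presets(),
       mrmr = list(n_bins = 10, variant = "quotient"),
       feature_selection = "positive_importance",  # or "all", or top-k int
       index_split = "every_third")
}

#' Run the full estimation pipeline
#'
#' Orchestrates generate/load -> index feature table -> collinearity ->
#' MRMR ranking -> per-index linear calibration (every-third split) ->
#' train/validation split -> fit of the configured model presets ->
#' metrics per stage. Fully reproducible given the config seed.
#'
#' @param config a named list, or a path to a YAML/JSON config file, with
#'   any of: \code{seed}; \code{generator} ([generator_config()]
#'   overrides); \code{spectra_csv} (load instead of generate);
#'   \code{split} (\code{scheme} = "random"/"every_third", \code{fraction});
#'   \code{models} (subset of [model_presets()]); \code{mrmr}
#'   (\code{n_bins}, \code{variant}); \code{feature_selection}
#'   ("positive_importance", "all", or an integer top-k).
#' @return An object of class \code{run_report}: list with per-model
#'   training/validation [metrics()], the [mrmr_rank()] ranking, the
#'   [collinearity()] report, the per-index calibrations, selected
#'   features, config echo, seed and package version.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        chl_stop("chlorospec_config_error", "yaml package needed for YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  seed <- as.integer(cfg$seed)

  spectra <- if (!is.null(cfg$spectra_csv)) {
    read_spectra_csv(cfg$spectra_csv)
  } else {
    gen <- do.call(generator_config, utils::modifyList(list(seed = seed),
                                                       cfg$generator))
    generate_dataset(gen)
  }

  ft <- compute_feature_table(spectra)
  coll <- collinearity(ft)
  ranking <- mrmr_rank(ft, n_bins = cfg$mrmr$n_bins,
                       variant = cfg$mrmr$variant)

  # Table-3-style per-index simple linear calibrations on the ordered
  # every-third split.
  idx_split <- split_every_third(ft)
  index_calibration <- lapply(attr(ft, "feature_names"), function(nm) {
    tr <- idx_split$training; va <- idx_split$validation
    cal <- simple_linear_calibration(tr[[nm]], tr$chlorophyll)
    pred <- cal$intercept + cal$slope * va[[nm]]
    c(list(index = nm, r = cal$r, slope = cal$slope,
           intercept = cal$intercept),
      unclass(metrics(va$chlorophyll, pred)))
  })
  names(index_calibration) <- attr(ft, "feature_names")

  sel <- cfg$feature_selection
  features_used <- if (identical(sel, "all")) {
    attr(ft, "feature_names")
  } else if (is.numeric(sel)) {
    head(ranking$feature[ranking$importance > 0], sel)
  } else {
    ranking$feature[ranking$importance > 0]
  }
  if (!length(features_used))
    chl_stop("chlorospec_pipeline_error", "no features survived selection")

  ml_split <- if (identical(cfg$split$scheme, "every_third"))
    split_every_third(ft)
  else split_random(ft, fraction = cfg$split$fraction, seed = seed)
  Xtr <- feature_matrix(ml_split$training)[, features_used, drop = FALSE]
  Xva <- feature_matrix(ml_split$validation)[, features_used, drop = FALSE]
  ytr <- ml_split$training$chlorophyll
  yva <- ml_split$validation$chlorophyll

  models <- list()
  for (preset in cfg$models) {
    m <- fit_model(preset, Xtr, ytr, seed = seed + match(preset, model_presets()))
    models[[preset]] <- list(
      training = metrics(ytr, predict(m, Xtr)),
      validation = metrics(yva, predict(m, Xva)),
      summary = m$training_summary)
  }

  structure(list(models = models, mrmr = ranking, collinearity = coll,
                 index_calibration = index_calibration,
                 features_used = features_used,
                 n_training = length(ytr), n_validation = length(yva),
                 config = cfg, seed = seed,
                 version = as.character(utils::packageVersion("chlorospec"))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("chlorospec run_report (seed %d): %d training / %d validation samples\n",
              x$seed, x$n_training, x$n_validation))
  cat("features:", paste(x$features_used, collapse = ", "), "\n")
  for (nm in names(x$models)) {
    v <- x$models[[nm]]$validation
    cat(sprintf("  %-18s validation R2 %.3f  RMSE %.1f  MAE %.1f\n",
                nm, v$r2, v$rmse, v$mae))
  }
  invisible(x)
}

#' Serialize a run report
#'
#' Writes \code{report.json} (full report) and \code{model_metrics.csv}
#' (one row per model and stage, five statistics per row) into a directory.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_run_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- do.call(rbind, lapply(names(report$models), function(nm) {
    rbind(cbind(model = nm, stage = "training",
                as.data.frame(report$models[[nm]]$training)),
          cbind(model = nm, stage = "validation",
                as.data.frame(report$models[[nm]]$validation)))
  }))
  utils::write.csv(rows, file.path(dir, "model_metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  ser <- list(models = lapply(report$models, function(m)
                list(training = unclass(m$training),
                     validation = unclass(m$validation))),
              mrmr = as.data.frame(report$mrmr),
              collinearity = as.data.frame(report$collinearity),
              index_calibration = report$index_calibration,
              features_used = report$features_used,
              n_training = report$n_training,
              n_validation = report$n_validation,
              seed = report$seed, version = report$version)
  jsonlite::write_json(ser, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
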