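#' Cross-validated benchmark of single classifiers
#'
#' Scores each roster entry on its own (all features, no ensemble) under
#' stratified k-fold cross-validation, pooling the confusion counts over
#' folds — the per-classifier comparison table with FPR, FRR, accuracy and
#' weighted cost per row.
#'
#' @param data Feature tibble with 0/1 label column.
#' @param roster Named list of [learner_spec()]s, default
#'   [benchmark_roster()].
#' @param k_folds Cross-validation folds.
#' @param weights A [cost_weights()] vector.
#' @param label Label column name.
#' @param seed Seed for fold assignment (and any stochastic learner).
#' @return A tibble, one row per learner, with confusion counts, rates and
#'   `cost`.
#' @export
benchmark_learners <- function(data, roster = benchmark_roster(),
                               k_folds = 10, weights = cost_weights(),
                               label = "class", seed = 1) {
  if (length(roster) == 0) {
    abort("Empty roster.", class = "efsemble_error_config")
  }
  set.seed(seed)
  fm <- feature_matrix(data, label)
  fold_idx <- split_folds(stratified_folds(fm$y, k_folds))
  full_mask <- rep(TRUE, ncol(fm$x))
  rows <- purrr::imap(roster, function(spec, name) {
    truth <- integer(0); pred <- integer(0)
    for (f in fold_idx) {
      fit <- fit_learner_xy(spec, fm$x[f$train, , drop = FALSE],
                            fm$y[f$train], full_mask)
      pred <- c(pred, predict_learner_x(fit, fm$x[f$test, , drop = FALSE]))
      truth <- c(truth, fm$y[f$test])
    }
    score_predictions(truth, pred, weights) |>
      dplyr::mutate(learner = name, description = spec$label,
                    .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Paired ensemble benchmark: equal-weight baseline vs optimised chromosome
#'
#' Compares, on identical folds, the plain ensemble (`EC`: equal weights,
#' all features for every learner) against the genetically optimised
#' two-layer chromosome (`EC+EFS(GA)`). Both are scored by cross-validated
#' confusion counts pooled over the same stratified folds the search used.
#'
#' The optimised row inherits the selection bias of choosing the best
#' chromosome by the same cross-validation it is reported on; the paired
#' direction (optimised cost at or below baseline cost) is the meaningful
#' readout, not the absolute level.
#'
#' @param data Feature tibble with 0/1 label column.
#' @param config A [ga_config()].
#' @param roster Ensemble roster, default [ensemble_roster()].
#' @param label Label column name.
#' @param seed Run seed.
#' @return A tibble with two rows (`EC`, `EC+EFS(GA)`) of counts, rates and
#'   `cost`; attribute `ga_fit` carries the underlying run.
#' @export
benchmark_ensemble <- function(data, config = ga_config(),
                               roster = ensemble_roster(), label = "class",
                               seed = 1) {
  run <- ga_fit(data, config, roster, label, seed = seed)
  R <- length(roster)
  N <- ncol(run$best_chromosome$fs)
  ec <- chromosome(
    el = rep(1 / R, R),
    fs = matrix(TRUE, R, N, dimnames = dimnames(run$best_chromosome$fs))
  )
  ec_rec <- evaluate_chromosome(ec, data, config, roster, label,
                                folds = run$folds)
  row_of <- function(name, rec) {
    rates <- classification_rates(rec$counts)
    dplyr::mutate(rates,
                  cost = rec$cost,
                  method = name, .before = 1)
  }
  out <- dplyr::bind_rows(
    row_of("EC", ec_rec),
    row_of("EC+EFS(GA)", list(counts = run$best_counts, cost = run$best_cost))
  )
  attr(out, "ga_fit") <- run
  out
}

#' Format a metrics table at fixed display precision
#'
#' Rounds the rate and cost columns half-up to 4 decimals, the precision of
#' published comparison tables.
#'
#' @param report A tibble from [benchmark_learners()] or
#'   [benchmark_ensemble()].
#' @return The report with rounded rate columns.
#' @export
format_metrics_report <- function(report) {
  dplyr::mutate(
    report,
    dplyr::across(dplyr::any_of(c("fpr", "frr", "err", "accuracy", "cost")),
                  ~ round_half_up(.x, 4))
  )
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the subcommand, the full
#' configuration, the seed, input-file digests and the artifacts written.
#'
#' @param path Output JSON path.
#' @param subcommand Name of the pipeline step.
#' @param config Configuration object (list-like) used for the run.
#' @param seed Integer seed.
#' @param inputs,outputs Character vectors of file paths; existing inputs
#'   are digested with MD5.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, subcommand, config, seed,
                               inputs = character(), outputs = character()) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else {
    list()
  }
  jsonlite::write_json(
    list(
      subcommand = subcommand,
      package_version = as.character(utils::packageVersion("efsemble")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
      seed = seed,
      config = unclass(config),
      input_digests = digests,
      outputs = as.list(outputs)
    ),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
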