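#' Repeat the genetic search with staggered seeds
#'
#' Because the search is stochastic, a single run's selected features are
#' noisy; feature-impact ranking aggregates the best chromosomes of many
#' independent runs (at least 30 in the reference protocol). Run `i` uses
#' seed `base_seed + i - 1`.
#'
#' @inheritParams ga_fit
#' @param n_runs Number of independent runs (>= 1).
#' @param base_seed Seed of the first run.
#' @return List of `ga_fit` objects, length `n_runs`.
#' @export
repeat_ga_runs <- function(data, config = ga_config(),
                           roster = ensemble_roster(), label = "class",
                           n_runs = 30, base_seed = 1) {
  if (n_runs < 1) abort("Need n_runs >= 1.", class = "efsemble_error_config")
  lapply(seq_len(n_runs) - 1L, function(i) {
    ga_fit(data, config, roster, label, seed = base_seed + i)
  })
}

#' Feature-impact percentages across repeated runs
#'
#' Converts the feature selections of repeated best chromosomes into a
#' per-feature impact percentage. Three averaging units are offered:
#' * `per_slot` (default) — the share of (run x learner) selection cells
#'   that include the feature.
#' * `any_learner` — the share of runs in which any learner selects it.
#' * `weight_weighted` — the learner-weight-normalised selection share per
#'   run, averaged over runs.
#'
#' `per_slot` and `any_learner` coincide when the roster has one learner.
#'
#' @param runs List of `ga_fit` objects with a common feature set.
#' @param mode Averaging unit, see above.
#' @return An `importance_report`: a tibble with `feature`, `impact`
#'   (percent, in `[0, 100]`) and `rank`, sorted by descending impact, with
#'   attributes `mode` and `n_runs`.
#' @export
impact_percentages <- function(runs,
                               mode = c("per_slot", "any_learner",
                                        "weight_weighted")) {
  mode <- match.arg(mode)
  if (length(runs) == 0) {
    abort("Need at least one run.", class = "efsemble_error_value")
  }
  feats <- colnames(runs[[1]]$best_chromosome$fs)
  per_run <- lapply(runs, function(r) {
    fs <- r$best_chromosome$fs
    if (!identical(colnames(fs), feats)) {
      abort("Runs disagree on the feature set.",
            class = "efsemble_error_consistency")
    }
    switch(
      mode,
      per_slot = colMeans(fs),
      any_learner = as.numeric(colSums(fs) > 0),
      weight_weighted = {
        el <- r$best_chromosome$el
        as.numeric(crossprod(fs, el) / sum(el))
      }
    )
  })
  impact <- 100 * colMeans(do.call(rbind, per_run))
  out <- tibble(feature = feats, impact = unname(impact)) |>
    dplyr::arrange(dplyr::desc(.data$impact)) |>
    dplyr::mutate(rank = dplyr::row_number())
  attr(out, "mode") <- mode
  attr(out, "n_runs") <- length(runs)
  class(out) <- c("importance_report", class(out))
  out
}

#' Horizontal bar chart of feature impacts
#'
#' @param object An `importance_report` from [impact_percentages()].
#' @param top Show only the `top` highest-impact features (default all).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.importance_report <- function(object, top = Inf, ...) {
  df <- head(as_tibble(object), top)
  ggplot2::ggplot(df, ggplot2::aes(.data$impact,
                                   stats::reorder(.data$feature,
                                                  .data$impact))) +
    ggplot2::geom_col(fill = "#2171b5") +
    ggplot2::labs(x = "impact (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Write an importance report as CSV
#'
#' @param report An `importance_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_importance_report <- function(report, path) {
  out <- dplyr::mutate(
    as_tibble(report),
    mode = attr(report, "mode"),
    n_runs = attr(report, "n_runs")
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Alignment coding-flip experiment
#'
#' Repeats the whole importance pipeline twice on the same raw cohort, once
#' per alignment coding (aligned = 0 then aligned = 1), so the stability of
#' the dominant-hand/involved-side alignment feature's impact can be
#' compared across codings. Both arms share `base_seed`, making the arms a
#' paired comparison.
#'
#' @param raw A raw patient tibble containing `dominant_hand` and
#'   `involved_side` columns (e.g. from [simulate_cohort()]).
#' @param config A [ga_config()].
#' @param n_runs_each Repeat runs per coding.
#' @param base_seed Seed shared by both arms.
#' @param mode Averaging unit passed to [impact_percentages()].
#' @param balance_factor Minority replication passed to
#'   [finalize_features()].
#' @param roster Base-learner roster.
#' @return A tibble of both importance reports with a `coding` column;
#'   attribute `alignment_impact` holds the alignment feature's impact under
#'   each coding.
#' @export
coding_flip_experiment <- function(raw, config = ga_config(),
                                   n_runs_each = 3, base_seed = 1,
                                   mode = "per_slot", balance_factor = 1,
                                   roster = ensemble_roster()) {
  if (!all(c("dominant_hand", "involved_side") %in% names(raw))) {
    abort("Raw table must carry `dominant_hand` and `involved_side`.",
          class = "efsemble_error_schema")
  }
  one_arm <- function(coding) {
    d <- derive_features(raw)
    d$alignment <- encode_alignment(d$dominant_hand, d$involved_side, coding)
    d <- d[setdiff(names(d), c("dominant_hand", "involved_side"))]
    ft <- finalize_features(d, balance_factor = balance_factor)
    runs <- repeat_ga_runs(ft, config, roster, n_runs = n_runs_each,
                           base_seed = base_seed)
    impact_percentages(runs, mode)
  }
  reports <- lapply(c("aligned_is_zero", "aligned_is_one"), one_arm)
  out <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(reports[[1]]), coding = "aligned_is_zero"),
    dplyr::mutate(as_tibble(reports[[2]]), coding = "aligned_is_one")
  )
  attr(out, "alignment_impact") <- setNames(
    vapply(reports, function(r) r$impact[r$feature == "alignment"],
           numeric(1)),
    c("aligned_is_zero", "aligned_is_one")
  )
  out
}
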