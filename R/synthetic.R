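#' Simulate a lymphedema-like clinical cohort
#'
#' Generates a raw patient table with the structure the preprocessing recipes
#' expect: birth/diagnosis/referral dates, height and weight, removed and
#' involved lymph-node counts, dominant-hand and involved-side tokens, an
#' edema volume consistent with the class label around the 200 mL rule, and
#' a block of additional clinical features with a planted informative subset.
#'
#' Class-conditional marginals for age, BMI and node counts follow the
#' descriptive statistics of a referral-clinic lymphedema cohort (mean age
#' 50.19 vs 48.0 years, BMI 28.95 vs 27.36, removed nodes 11.99 vs 11.44,
#' involved nodes 4.09 vs 2.05 for cases vs controls). Edema volume is drawn
#' from class-conditional lognormal tails of the 200 mL boundary so labelling
#' by volume reproduces the generated class exactly.
#'
#' Informative clinical features cycle through continuous / binary / ordinal
#' kinds. A continuous informative feature is shifted by `effect_size`
#' standard deviations in the case class; a binary one has success
#' probability `plogis(effect_size / 2)` for cases versus
#' `plogis(-effect_size / 2)` for controls; an ordinal one is a discretised
#' shifted Gaussian. Noise features are identically distributed in both
#' classes.
#'
#' @param n_pos,n_neg Class sizes (cases, controls); defaults 740 / 230.
#' @param n_informative Number of informative clinical features (default 6).
#' @param n_noise Number of uninformative clinical features (default 24).
#' @param effect_size Standardised class shift for informative features
#'   (default 1).
#' @param alignment_effect Log-odds by which limb/hand *misalignment* is more
#'   likely among cases; 0 (default) makes alignment pure noise.
#' @param missing_rate Either a single MCAR missingness rate applied to the
#'   `nodes_involved` column, or a named vector of per-column rates.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A tibble of raw patient records, in randomised row order, with
#'   attributes `ground_truth` (informative feature names and effect sizes)
#'   and `schema` (a [patient_schema()] for the table).
#' @export
simulate_cohort <- function(n_pos = 740, n_neg = 230,
                            n_informative = 6, n_noise = 24,
                            effect_size = 1, alignment_effect = 0,
                            missing_rate = 0, seed = 1) {
  stopifnot(n_pos >= 1, n_neg >= 1, n_informative >= 0, n_noise >= 0)
  set.seed(seed)
  n <- n_pos + n_neg
  class <- c(rep(1L, n_pos), rep(0L, n_neg))

  age <- rnorm(n, mean = ifelse(class == 1, 50.19, 48.0),
               sd = ifelse(class == 1, 11.12, 10.75))
  age <- pmax(age, 20)
  diagnosis_date <- as.Date("2015-06-01") + round(runif(n, -1500, 1500))
  date_of_birth <- diagnosis_date - round(age * 365.25 + runif(n, 0, 364))
  referral_date <- diagnosis_date + round(runif(n, 30, 2000))

  height <- rnorm(n, 1.60, 0.06)
  bmi <- pmax(rnorm(n, mean = ifelse(class == 1, 28.95, 27.36),
                    sd = ifelse(class == 1, 5.14, 5.10)), 15)
  weight <- round(bmi * height^2, 1)
  height <- round(height, 2)

  nodes_removed <- pmax(1L, as.integer(round(
    rnorm(n, mean = ifelse(class == 1, 11.99, 11.44), sd = 6.0)
  )))
  nodes_involved <- pmin(
    nodes_removed,
    pmax(0L, as.integer(round(
      rnorm(n, mean = ifelse(class == 1, 4.09, 2.05), sd = 4.5)
    )))
  )

  dominant_hand <- sample(c("right", "left"), n, TRUE, prob = c(0.9, 0.1))
  p_misaligned <- stats::plogis(
    stats::qlogis(0.5) + alignment_effect * (class == 1)
  )
  misaligned <- rbinom(n, 1, p_misaligned) == 1
  involved_side <- ifelse(misaligned,
                          ifelse(dominant_hand == "right", "left", "right"),
                          dominant_hand)

  # volumes: cases strictly above 200 mL, controls at or below
  edema_volume_ml <- ifelse(
    class == 1,
    200 + stats::rlnorm(n, meanlog = 5.0, sdlog = 0.9),
    200 * exp(-abs(rnorm(n, 0, 0.8)))
  )
  edema_volume_ml <- round(edema_volume_ml, 1)

  tab <- tibble(
    date_of_birth, diagnosis_date, referral_date,
    height, weight, nodes_removed, nodes_involved,
    dominant_hand, involved_side, edema_volume_ml
  )

  kinds <- c(continuous = "continuous", binary = "binary", ordinal = "ordinal")
  truth_names <- character(0)
  truth_effects <- numeric(0)
  add_feature <- function(tab, name, kind, effect) {
    if (kind == "continuous") {
      tab[[name]] <- rnorm(n, mean = effect * (class == 1), sd = 1)
    } else if (kind == "binary") {
      p <- stats::plogis(ifelse(class == 1, effect / 2, -effect / 2))
      tab[[name]] <- rbinom(n, 1, p)
    } else {
      z <- rnorm(n, mean = effect * (class == 1), sd = 1)
      tab[[name]] <- as.integer(cut(z, breaks = c(-Inf, -0.5, 0.5, 1.5, Inf))) - 1L
    }
    tab
  }
  kind_cycle <- rep(c("continuous", "binary", "ordinal"),
                    length.out = n_informative + n_noise)
  for (i in seq_len(n_informative)) {
    name <- sprintf("sig_%s_%02d", substr(kind_cycle[i], 1, 3), i)
    tab <- add_feature(tab, name, kind_cycle[i], effect_size)
    truth_names <- c(truth_names, name)
    truth_effects <- c(truth_effects, effect_size)
  }
  for (j in seq_len(n_noise)) {
    i <- n_informative + j
    name <- sprintf("noise_%s_%02d", substr(kind_cycle[i], 1, 3), j)
    tab <- add_feature(tab, name, kind_cycle[i], 0)
  }

  # MCAR missingness
  if (is.null(names(missing_rate))) {
    missing_rate <- if (missing_rate[1] > 0) {
      c(nodes_involved = missing_rate[1])
    } else {
      numeric(0)
    }
  }
  for (col in names(missing_rate)) {
    hit <- runif(n) < missing_rate[[col]]
    tab[[col]][hit] <- NA
  }

  tab <- tab[sample.int(n), , drop = FALSE]

  feature_kinds <- setNames(kind_cycle, c(truth_names, grep("^noise_", names(tab), value = TRUE)))
  schema <- patient_schema(
    c(
      date_of_birth = "date", diagnosis_date = "date", referral_date = "date",
      height = "continuous", weight = "continuous",
      nodes_removed = "ordinal", nodes_involved = "ordinal",
      dominant_hand = "categorical", involved_side = "categorical",
      edema_volume_ml = "continuous",
      feature_kinds
    ),
    required = c("nodes_removed", "nodes_involved", "edema_volume_ml",
                 "height", "weight")
  )
  attr(tab, "schema") <- schema
  attr(tab, "ground_truth") <- list(
    informative = truth_names,
    effect_sizes = setNames(truth_effects, truth_names),
    alignment_effect = alignment_effect,
    n_pos = n_pos, n_neg = n_neg, seed = seed
  )
  tab
}

#' Simulate a ready-to-model feature table with planted signal
#'
#' Skips the raw-table stage and draws a numeric feature table directly:
#' `n_informative` class-shifted features (cycling continuous / binary /
#' ordinal kinds as in [simulate_cohort()]) plus `n_noise` features identical
#' across classes, and a 0/1 `class` column.
#'
#' @inheritParams simulate_cohort
#' @return A feature tibble with `class` column and a `ground_truth`
#'   attribute naming the informative features.
#' @export
simulate_feature_table <- function(n_pos = 740, n_neg = 230,
                                   n_informative = 6, n_noise = 24,
                                   effect_size = 1, seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  class <- c(rep(1L, n_pos), rep(0L, n_neg))
  tab <- tibble(.rows = n)
  kind_cycle <- rep(c("continuous", "binary", "ordinal"),
                    length.out = n_informative + n_noise)
  truth <- character(0)
  for (i in seq_len(n_informative + n_noise)) {
    informative <- i <= n_informative
    effect <- if (informative) effect_size else 0
    name <- sprintf("%s_%s_%02d", if (informative) "sig" else "noise",
                    substr(kind_cycle[i], 1, 3), i)
    if (kind_cycle[i] == "continuous") {
      tab[[name]] <- rnorm(n, mean = effect * (class == 1), sd = 1)
    } else if (kind_cycle[i] == "binary") {
      p <- stats::plogis(ifelse(class == 1, effect / 2, -effect / 2))
      tab[[name]] <- rbinom(n, 1, p)
    } else {
      z <- rnorm(n, mean = effect * (class == 1), sd = 1)
      tab[[name]] <- as.integer(cut(z, breaks = c(-Inf, -0.5, 0.5, 1.5, Inf))) - 1L
    }
    if (informative) truth <- c(truth, name)
  }
  tab$class <- class
  tab <- tab[sample.int(n), , drop = FALSE]
  attr(tab, "ground_truth") <- list(
    informative = truth,
    effect_sizes = setNames(rep(effect_size, length(truth)), truth),
    n_pos = n_pos, n_neg = n_neg, seed = seed
  )
  attr(tab, "class_counts") <- c(`0` = n_neg, `1` = n_pos)
  tab
}

#' Deterministic named fixtures
#'
#' Small seeded cohorts used throughout the test-suite and examples:
#' * `tiny` — 20 rows, 4 features, balanced; for hand-checkable oracles.
#' * `separable` — one feature separates the classes perfectly; a depth-1
#'   tree reaches 100% training accuracy.
#' * `null` — no informative features; classifiers should hover at the
#'   majority-class rate.
#' * `study_like` — 970 rows (740 cases / 230 controls), 30 features of
#'   which 6 are informative; the end-to-end benchmark cohort.
#'
#' @param name One of `"tiny"`, `"separable"`, `"null"`, `"study_like"`.
#' @return A feature tibble with `class` column; identical on every call.
#' @export
make_fixture <- function(name = c("tiny", "separable", "null", "study_like")) {
  name <- match.arg(name)
  switch(
    name,
    tiny = simulate_feature_table(
      n_pos = 10, n_neg = 10, n_informative = 2, n_noise = 2,
      effect_size = 2, seed = 11
    ),
    separable = {
      set.seed(12)
      n <- 60
      class <- rep(c(0L, 1L), each = n / 2)
      tab <- tibble(
        x_gap = ifelse(class == 1, runif(n, 0.6, 1), runif(n, 0, 0.4)),
        x_noise1 = rnorm(n),
        x_noise2 = as.integer(rbinom(n, 1, 0.5)),
        class = class
      )
      tab[sample.int(n), , drop = FALSE]
    },
    null = simulate_feature_table(
      n_pos = 150, n_neg = 50, n_informative = 0, n_noise = 6,
      effect_size = 0, seed = 13
    ),
    study_like = simulate_feature_table(
      n_pos = 740, n_neg = 230, n_informative = 6, n_noise = 24,
      effect_size = 1, seed = 14
    )
  )
}
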