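#' Confusion counts under a target-class convention
#'
#' Tallies a binary confusion matrix in the acceptance/rejection vocabulary
#' used for screening problems: the *target* class (by default the healthy
#' class, label 0) is the class whose members the system should "accept".
#' A target-class case predicted non-target is a *false rejection*; a
#' non-target case predicted target is a *false acceptance*.
#'
#' @param truth Integer or numeric vector of observed labels in `{0, 1}`.
#' @param estimate Predicted labels, same length and alphabet as `truth`.
#' @param target_label Which label is the target (accepted) class. Default 0,
#'   the healthy/without-condition class.
#' @return A one-row tibble with columns `true_accept`, `false_reject`,
#'   `true_reject`, `false_accept`, `target_label`.
#' @examples
#' confusion_counts(c(0, 0, 1, 1), c(0, 1, 1, 0))
#' @export
confusion_counts <- function(truth, estimate, target_label = 0) {
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have the same length.",
          class = "efsemble_error_value")
  }
  check_binary_labels(truth, "truth")
  check_binary_labels(estimate, "estimate")
  is_target <- truth == target_label
  tibble(
    true_accept  = sum(is_target & estimate == target_label),
    false_reject = sum(is_target & estimate != target_label),
    true_reject  = sum(!is_target & estimate != target_label),
    false_accept = sum(!is_target & estimate == target_label),
    target_label = as.integer(target_label)
  )
}

#' Build confusion counts directly from the four cell values
#'
#' Convenience constructor used when reconstructing published confusion
#' matrices rather than tallying predictions.
#'
#' @param true_accept,false_reject,true_reject,false_accept Nonnegative counts.
#' @param target_label Target-class label, default 0.
#' @return A one-row tibble in the same shape as [confusion_counts()].
#' @export
as_confusion_counts <- function(true_accept, false_reject, true_reject,
                                false_accept, target_label = 0) {
  cells <- c(true_accept, false_reject, true_reject, false_accept)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("Confusion cells must be nonnegative integers.",
          class = "efsemble_error_value")
  }
  tibble(
    true_accept = as.integer(true_accept),
    false_reject = as.integer(false_reject),
    true_reject = as.integer(true_reject),
    false_accept = as.integer(false_accept),
    target_label = as.integer(target_label)
  )
}

#' Error rates from confusion counts
#'
#' Appends the biometric-style error decomposition to a confusion-count
#' table: `fpr` (false acceptance rate, non-target cases accepted as target),
#' `frr` (false rejection rate, target cases rejected), overall `accuracy`
#' and classification error `err = 1 - accuracy`.
#'
#' @param counts A tibble with the four confusion columns, as produced by
#'   [confusion_counts()]; multiple rows are allowed (one per classifier).
#' @return `counts` with columns `fpr`, `frr`, `err`, `accuracy` appended.
#' @examples
#' as_confusion_counts(637, 53, 630, 110) |> classification_rates()
#' @export
classification_rates <- function(counts) {
  target_total <- counts$true_accept + counts$false_reject
  nontarget_total <- counts$true_reject + counts$false_accept
  if (any(target_total == 0) || any(nontarget_total == 0)) {
    abort("Both classes must be represented to define FPR and FRR.",
          class = "efsemble_error_degenerate")
  }
  total <- target_total + nontarget_total
  dplyr::mutate(
    counts,
    fpr = .data$false_accept / nontarget_total,
    frr = .data$false_reject / target_total,
    accuracy = (.data$true_accept + .data$true_reject) / total,
    err = 1 - .data$accuracy
  )
}

#' Cost weights for the fitness objective
#'
#' The scalarised objective is `w_err * err + w_fpr * fpr + w_frr * frr`.
#' Weights are free nonnegative constants left to the analyst; a clinician
#' who considers a missed case worse than a false alarm would set
#' `w_fpr < w_frr`. The default weighs the three components equally.
#'
#' @param w_err,w_fpr,w_frr Nonnegative reals, not all zero.
#' @return A named numeric vector of length 3.
#' @export
cost_weights <- function(w_err = 1 / 3, w_fpr = 1 / 3, w_frr = 1 / 3) {
  w <- c(err = w_err, fpr = w_fpr, frr = w_frr)
  if (any(w < 0) || all(w == 0)) {
    abort("Cost weights must be nonnegative and not all zero.",
          class = "efsemble_error_config")
  }
  w
}

#' Weighted misclassification cost
#'
#' Evaluates the scalar cost `w_err * err + w_fpr * fpr + w_frr * frr` on a
#' rate table, the quantity the genetic search minimises.
#'
#' @param rates A tibble carrying `err`, `fpr`, `frr` columns (see
#'   [classification_rates()]); confusion columns alone are also accepted and
#'   rates are derived first.
#' @param weights A [cost_weights()] vector.
#' @return Numeric vector, one cost per row of `rates`.
#' @examples
#' as_confusion_counts(637, 53, 630, 110) |>
#'   classification_rates() |>
#'   classification_cost()
#' @export
classification_cost <- function(rates, weights = cost_weights()) {
  if (!all(c("err", "fpr", "frr") %in% names(rates))) {
    rates <- classification_rates(rates)
  }
  unname(weights["err"] * rates$err +
         weights["fpr"] * rates$fpr +
         weights["frr"] * rates$frr)
}

#' Score predictions in one call
#'
#' Tallies the confusion matrix, derives rates and appends the weighted cost:
#' the row format used throughout the benchmark reports.
#'
#' @inheritParams confusion_counts
#' @param weights A [cost_weights()] vector.
#' @return A one-row tibble with counts, rates and `cost`.
#' @export
score_predictions <- function(truth, estimate, weights = cost_weights(),
                              target_label = 0) {
  counts <- confusion_counts(truth, estimate, target_label = target_label)
  rates <- classification_rates(counts)
  dplyr::mutate(rates, cost = classification_cost(rates, weights))
}

#' Round half away from zero
#'
#' Display rounding matching fixed-precision published tables, where 0.00005
#' rounds up to 0.0001 (base R `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 4) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

check_binary_labels <- function(x, name) {
  if (length(x) == 0 || !all(x %in% c(0, 1))) {
    abort(paste0("`", name, "` must be a non-empty vector of 0/1 labels."),
          class = "efsemble_error_value")
  }
  invisible(x)
}
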