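#' Two-layer ensemble chromosome
#'
#' One candidate solution of the joint search: a weight vector `el` over the
#' R base learners (each weight in `[0, 1]`) and a binary R x N matrix `fs`
#' whose row j selects the feature subset base learner j is trained on.
#' Weights are raw, not simplex-constrained: the vote normalises by their
#' sum, so any positive rescaling of `el` yields identical predictions.
#'
#' @param el Numeric vector of learner weights in `[0, 1]`, length R, at
#'   least one strictly positive.
#' @param fs Logical or 0/1 matrix, R rows by N feature columns, each row
#'   with at least one selected feature.
#' @param learners,features Optional dimension names.
#' @return A `chromosome` object.
#' @export
chromosome <- function(el, fs, learners = rownames(fs),
                       features = colnames(fs)) {
  fs <- matrix(as.logical(fs), nrow = nrow(as.matrix(fs)),
               dimnames = list(learners, features))
  obj <- structure(list(el = as.numeric(el), fs = fs), class = "chromosome")
  validate_chromosome(obj, mode = "reject")
}

#' Validate or repair a chromosome
#'
#' The search operators can produce degenerate candidates (an all-zero
#' feature row, an all-zero weight vector). In `"reject"` mode a violation
#' raises; in `"repair"` mode an all-zero `fs` row gets one uniformly chosen
#' bit set and an all-zero `el` is reset to uniform weights, keeping the
#' operators closed over the feasible space.
#'
#' @param c A chromosome (possibly invalid) as a `list(el, fs)`.
#' @param mode `"reject"` or `"repair"`.
#' @return A valid `chromosome`.
#' @export
validate_chromosome <- function(c, mode = c("reject", "repair")) {
  mode <- match.arg(mode)
  el <- as.numeric(c$el)
  fs <- c$fs
  if (length(el) != nrow(fs)) {
    abort("Length of `el` must equal the number of `fs` rows.",
          class = "efsemble_error_chromosome")
  }
  if (any(el < 0 | el > 1)) {
    if (mode == "reject") {
      abort("Learner weights must lie in [0, 1].",
            class = "efsemble_error_chromosome")
    }
    el <- pmin(pmax(el, 0), 1)
  }
  empty_rows <- rowSums(fs) == 0
  if (any(empty_rows)) {
    if (mode == "reject") {
      abort("Every feature-selection row needs at least one selected feature.",
            class = "efsemble_error_chromosome")
    }
    for (j in which(empty_rows)) {
      fs[j, sample.int(ncol(fs), 1)] <- TRUE
    }
  }
  if (sum(el) == 0) {
    if (mode == "reject") {
      abort("At least one learner weight must be strictly positive.",
            class = "efsemble_error_chromosome")
    }
    el <- rep(1 / length(el), length(el))
  }
  structure(list(el = el, fs = fs), class = "chromosome")
}

#' @export
print.chromosome <- function(x, ...) {
  cat(sprintf("<chromosome> %d learners x %d features\n",
              nrow(x$fs), ncol(x$fs)))
  cat("  weights:", paste(sprintf("%.3f", x$el), collapse = " "), "\n")
  cat("  features/learner:", paste(rowSums(x$fs), collapse = " "), "\n")
  invisible(x)
}

#' Tidy a chromosome into a learner-by-feature tibble
#'
#' @param x A `chromosome`.
#' @param ... Unused.
#' @return A tibble with columns `learner`, `weight`, `feature`, `selected`.
#' @exportS3Method generics::tidy
tidy.chromosome <- function(x, ...) {
  learners <- rownames(x$fs) %||% paste0("learner_", seq_len(nrow(x$fs)))
  features <- colnames(x$fs) %||% paste0("feature_", seq_len(ncol(x$fs)))
  tidyr::expand_grid(learner = learners, feature = features) |>
    dplyr::mutate(
      weight = rep(x$el, each = length(features)),
      selected = as.vector(t(x$fs))
    ) |>
    dplyr::select("learner", "weight", "feature", "selected")
}

#' Weight-normalised vote score
#'
#' The ensemble score for one case: `sum(el * votes) / sum(el)`, in
#' `[0, 1]`. Accepts a vote matrix (rows = cases, columns = learners) for
#' vectorised use.
#'
#' @param votes Binary vector of length R, or an n x R binary matrix.
#' @param el Learner weights with positive sum.
#' @return Numeric score(s) in `[0, 1]`.
#' @examples
#' weighted_vote(c(1, 0, 1, 0, 0), c(0.5, 0.3, 0.2, 0, 0))  # 0.7
#' @export
weighted_vote <- function(votes, el) {
  s <- sum(el)
  if (s <= 0) {
    abort("Weight sum must be positive.", class = "efsemble_error_chromosome")
  }
  if (is.matrix(votes)) {
    as.numeric(votes %*% el) / s
  } else {
    sum(el * votes) / s
  }
}

#' Threshold a vote score to a label
#'
#' Scores at or above the threshold map to 1; the tie at exactly the
#' threshold goes to 1 by convention. Default threshold 0.5, the midpoint of
#' the normalised score.
#'
#' @param score Numeric score(s) in `[0, 1]`.
#' @param threshold Decision threshold in `(0, 1]`.
#' @return Integer 0/1 label(s).
#' @export
threshold_label <- function(score, threshold = 0.5) {
  if (threshold <= 0 || threshold > 1) {
    abort("`threshold` must lie in (0, 1].", class = "efsemble_error_config")
  }
  as.integer(score >= threshold)
}

#' Ensemble prediction under a chromosome
#'
#' Collects each trained learner's hard votes, combines them by the
#' weight-normalised vote and thresholds to a label. The fitted learners
#' must carry exactly the masks of the chromosome's `fs` rows.
#'
#' @param chrom A [chromosome()].
#' @param learners List of `trained_learner` objects, one per `fs` row, in
#'   row order.
#' @param data Feature tibble to predict on.
#' @param threshold Decision threshold, default 0.5.
#' @return A tibble with one row per case: `score`, `label`, and one
#'   `vote_<learner>` column per base learner.
#' @export
ensemble_predict <- function(chrom, learners, data, threshold = 0.5) {
  if (length(learners) != nrow(chrom$fs)) {
    abort("Need one trained learner per chromosome row.",
          class = "efsemble_error_consistency")
  }
  for (j in seq_along(learners)) {
    if (!identical(as.logical(learners[[j]]$mask),
                   as.logical(chrom$fs[j, ]))) {
      abort(sprintf("Learner %d was fitted under a different mask.", j),
            class = "efsemble_error_consistency")
    }
  }
  votes <- vapply(learners, function(l) predict(l, data),
                  integer(nrow(data)))
  votes <- matrix(votes, nrow = nrow(data))
  score <- weighted_vote(votes, chrom$el)
  out <- tibble(score = score, label = threshold_label(score, threshold))
  nm <- rownames(chrom$fs) %||% paste0("learner_", seq_along(learners))
  for (j in seq_along(learners)) out[[paste0("vote_", nm[j])]] <- votes[, j]
  out
}

#' Serialise a chromosome to JSON (and back)
#'
#' @param x A `chromosome`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
chromosome_to_json <- function(x, path = NULL) {
  payload <- list(
    el = x$el,
    fs = apply(x$fs, 1, function(r) paste(as.integer(r), collapse = "")),
    learners = rownames(x$fs),
    features = colnames(x$fs)
  )
  if (is.null(path)) {
    jsonlite::toJSON(payload, auto_unbox = TRUE)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
  }
}

#' @rdname chromosome_to_json
#' @param json A JSON string or file path produced by [chromosome_to_json()].
#' @export
chromosome_from_json <- function(json) {
  payload <- if (file.exists(json)) {
    jsonlite::read_json(json, simplifyVector = TRUE)
  } else {
    jsonlite::fromJSON(json)
  }
  fs <- t(vapply(strsplit(payload$fs, ""),
                 function(r) as.integer(r) == 1L,
                 logical(nchar(payload$fs[1]))))
  chromosome(payload$el, fs, learners = payload$learners,
             features = payload$features)
}
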