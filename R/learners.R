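#' Declare a base learner
#'
#' A light specification of one classifier in the ensemble roster. Supported
#' kinds and their hyperparameters:
#' * `knn` — k-nearest neighbours, `k` (default 3). Vote ties resolve to the
#'   lower label.
#' * `svm` — support vector machine, `kernel` in `"linear"`, `"rbf"`,
#'   `"polynomial"` (default `"rbf"`), `cost`, `degree`.
#' * `lda` — linear discriminant analysis.
#' * `bayes` — naive Bayes with Gaussian likelihoods for numeric columns.
#' * `tree` — decision tree split on information (entropy) gain, the
#'   C4.5-family default; `maxdepth`, `cp`.
#' * `mlp` — single-hidden-layer perceptron, `size` (default 16), `maxit`,
#'   `decay`.
#'
#' Distance-based kinds (`knn`, `svm`, `mlp`) standardise features to
#' zero mean and unit variance using training-set statistics.
#'
#' @param kind One of `"knn"`, `"svm"`, `"lda"`, `"bayes"`, `"tree"`, `"mlp"`.
#' @param k Neighbours for `knn`.
#' @param kernel,cost,degree SVM kernel and parameters.
#' @param maxdepth,cp Tree depth limit and complexity parameter.
#' @param size,maxit,decay MLP hidden units, iteration cap and weight decay.
#' @return A `learner_spec` object.
#' @export
learner_spec <- function(kind = c("knn", "svm", "lda", "bayes", "tree", "mlp"),
                         k = 3, kernel = "rbf", cost = 1, degree = 3,
                         maxdepth = 30, cp = 0.01,
                         size = 16, maxit = 200, decay = 1e-3) {
  kind <- match.arg(kind)
  params <- switch(
    kind,
    knn = list(k = k),
    svm = list(kernel = kernel, cost = cost, degree = degree,
               tolerance = 0.01),
    lda = list(),
    bayes = list(),
    tree = list(maxdepth = maxdepth, cp = cp),
    mlp = list(size = size, maxit = maxit, decay = decay)
  )
  if (kind == "knn" && params$k < 1) {
    abort("knn needs k >= 1.", class = "efsemble_error_config")
  }
  if (kind == "svm" &&
      !params$kernel %in% c("linear", "rbf", "polynomial")) {
    abort("svm kernel must be linear, rbf or polynomial.",
          class = "efsemble_error_config")
  }
  label <- switch(
    kind,
    knn = sprintf("KNN (k=%d)", params$k),
    svm = sprintf("SVM (%s)", params$kernel),
    lda = "LDA",
    bayes = "Bayes",
    tree = "Tree (C4.5-like)",
    mlp = sprintf("MLP (%d)", params$size)
  )
  structure(list(kind = kind, params = params, label = label),
            class = "learner_spec")
}

#' @export
print.learner_spec <- function(x, ...) {
  cat("<learner_spec>", x$label, "\n")
  invisible(x)
}

#' The five-learner ensemble roster
#'
#' KNN (k = 3), SVM with RBF kernel, LDA, naive Bayes and an entropy-split
#' decision tree: the heterogeneous set combined by the weighted vote.
#'
#' @return A named list of [learner_spec()] objects, length 5.
#' @export
ensemble_roster <- function() {
  list(
    knn = learner_spec("knn", k = 3),
    svm = learner_spec("svm", kernel = "rbf"),
    bayes = learner_spec("bayes"),
    tree = learner_spec("tree"),
    lda = learner_spec("lda")
  )
}

#' The eight-learner single-classifier benchmark roster
#'
#' The ensemble roster plus the remaining SVM kernels and the MLP, used for
#' the per-classifier comparison table.
#'
#' @return A named list of [learner_spec()] objects, length 8.
#' @export
benchmark_roster <- function() {
  list(
    svm_linear = learner_spec("svm", kernel = "linear"),
    svm_rbf = learner_spec("svm", kernel = "rbf"),
    svm_polynomial = learner_spec("svm", kernel = "polynomial"),
    lda = learner_spec("lda"),
    knn = learner_spec("knn", k = 3),
    bayes = learner_spec("bayes"),
    tree = learner_spec("tree"),
    mlp = learner_spec("mlp")
  )
}

# Split a feature tibble into the numeric matrix and label vector the
# adapters consume.
feature_matrix <- function(data, label = "class") {
  if (!label %in% names(data)) {
    abort(paste0("Label column `", label, "` not found."),
          class = "efsemble_error_schema")
  }
  y <- as.integer(data[[label]])
  check_binary_labels(y, label)
  x <- as.matrix(data[setdiff(names(data), label)])
  storage.mode(x) <- "double"
  list(x = x, y = y, features = colnames(x))
}

#' Fit a base learner on a masked feature subset
#'
#' Trains `spec` on the columns of `data` selected by `mask`; the mask is
#' stored so prediction uses exactly the same subset. Predictions can never
#' depend on unselected columns.
#'
#' Degenerate fits (e.g. LDA on columns that are constant in the training
#' rows) fall back to a majority-class constant predictor rather than
#' aborting a surrounding stochastic search; the fallback is recorded in the
#' returned object.
#'
#' @param spec A [learner_spec()].
#' @param data A feature tibble with a 0/1 label column.
#' @param mask Logical or 0/1 vector over the feature columns (label
#'   excluded); `NULL` selects all features.
#' @param label Name of the label column, default `"class"`.
#' @return A `trained_learner` object.
#' @export
fit_learner <- function(spec, data, mask = NULL, label = "class") {
  fm <- feature_matrix(data, label)
  n_feat <- length(fm$features)
  if (is.null(mask)) mask <- rep(TRUE, n_feat)
  mask <- as.logical(mask)
  if (length(mask) != n_feat) {
    abort("`mask` length must equal the number of feature columns.",
          class = "efsemble_error_value")
  }
  if (!any(mask)) {
    abort("Mask selects no features.", class = "efsemble_error_mask")
  }
  if (length(unique(fm$y)) < 2) {
    abort("Training data contains a single class.",
          class = "efsemble_error_degenerate")
  }
  fit_learner_xy(spec, fm$x, fm$y, mask, fm$features)
}

# Matrix-level fitting; the hot path for the genetic search.
fit_learner_xy <- function(spec, x, y, mask, features = colnames(x)) {
  xm <- x[, mask, drop = FALSE]
  scaled <- spec$kind %in% c("knn", "svm", "mlp")
  center <- scale_sd <- NULL
  if (scaled) {
    center <- colMeans(xm)
    scale_sd <- col_sds(xm)
    scale_sd[scale_sd == 0 | is.na(scale_sd)] <- 1
    xm <- scale(xm, center = center, scale = scale_sd)
  }
  majority <- as.integer(names(which.max(table(y))))
  fallback <- FALSE
  model <- switch(
    spec$kind,
    knn = list(x = xm, y = y),
    svm = e1071::svm(
      xm, factor(y, levels = c(0, 1)),
      kernel = switch(spec$params$kernel, rbf = "radial", spec$params$kernel),
      degree = spec$params$degree, cost = spec$params$cost, scale = FALSE,
      fitted = FALSE, tolerance = spec$params$tolerance
    ),
    lda = {
      keep <- col_sds(xm) > 0
      m <- if (any(keep)) {
        tryCatch(MASS::lda(xm[, keep, drop = FALSE], grouping = y),
                 error = function(e) NULL)
      }
      if (is.null(m)) fallback <- TRUE
      list(fit = m, keep = keep)
    },
    bayes = {
      keep <- col_sds(xm) > 0
      m <- if (any(keep)) {
        fit_gaussian_nb(xm[, keep, drop = FALSE], y)
      }
      if (is.null(m)) fallback <- TRUE
      list(fit = m, keep = keep)
    },
    tree = {
      df <- as.data.frame(xm)
      df$.y <- factor(y, levels = c(0, 1))
      rpart::rpart(
        .y ~ ., data = df, method = "class",
        parms = list(split = "information"),
        control = rpart::rpart.control(
          xval = 0, maxdepth = spec$params$maxdepth, cp = spec$params$cp,
          maxcompete = 0, maxsurrogate = 0, usesurrogate = 0
        ),
        model = FALSE, y = FALSE
      )
    },
    mlp = nnet::nnet(
      xm, matrix(y, ncol = 1), size = spec$params$size,
      maxit = spec$params$maxit, decay = spec$params$decay,
      entropy = TRUE, trace = FALSE
    )
  )
  structure(
    list(spec = spec, model = model, mask = mask, features = features,
         center = center, scale = scale_sd, majority = majority,
         fallback = fallback),
    class = "trained_learner"
  )
}

#' Predict 0/1 labels from a trained base learner
#'
#' @param object A `trained_learner` from [fit_learner()].
#' @param data A feature tibble containing at least the masked columns (a
#'   label column, if present, is ignored).
#' @param ... Unused.
#' @return Integer vector of 0/1 labels, one per row.
#' @export
predict.trained_learner <- function(object, data, ...) {
  missing_cols <- setdiff(object$features[object$mask], names(data))
  if (length(missing_cols)) {
    abort(paste0("Masked column(s) absent from new data: ",
                 paste(missing_cols, collapse = ", ")),
          class = "efsemble_error_schema")
  }
  x <- as.matrix(data[object$features[object$mask]])
  storage.mode(x) <- "double"
  predict_learner_x(object, x)
}

col_sds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sqrt(pmax(colSums(x^2) - n * mu^2, 0) / (n - 1))
}

# Gaussian naive-Bayes fit in the shape of e1071::naiveBayes (class priors
# plus a per-feature 2 x (mean, sd) table), computed with column-wise
# arithmetic; equivalence with the e1071 fit is asserted in the tests.
fit_gaussian_nb <- function(x, y) {
  i0 <- y == 0
  n0 <- sum(i0); n1 <- sum(!i0)
  mu0 <- colMeans(x[i0, , drop = FALSE])
  mu1 <- colMeans(x[!i0, , drop = FALSE])
  sd0 <- col_sds(x[i0, , drop = FALSE])
  sd1 <- col_sds(x[!i0, , drop = FALSE])
  tables <- lapply(seq_len(ncol(x)), function(j) {
    rbind(`0` = c(mu0[j], sd0[j]), `1` = c(mu1[j], sd1[j]))
  })
  names(tables) <- colnames(x)
  list(apriori = c(`0` = n0, `1` = n1) / (n0 + n1), tables = tables)
}

# Vectorised decision values for a binary e1071::svm fit (libsvm):
# f(x) = sum_i coefs_i K(SV_i, x) - rho, classes split by sign of f.
# Equivalent to predict.svm, which pays heavy per-call na.action overhead.
svm_predict_decision <- function(fit, x) {
  sv <- fit$SV
  cross <- x %*% t(sv)
  K <- switch(
    fit$kernel + 1,
    cross,                                               # 0 linear
    (fit$gamma * cross + fit$coef0)^fit$degree,          # 1 polynomial
    {                                                    # 2 radial
      d2 <- outer(rowSums(x^2), rowSums(sv^2), `+`) - 2 * cross
      exp(-fit$gamma * pmax(d2, 0))
    }
  )
  decision <- as.numeric(K %*% fit$coefs) - fit$rho
  lev <- as.integer(fit$levels)   # levels are "0","1"
  as.integer(ifelse(decision > 0, lev[fit$labels[1]], lev[fit$labels[2]]))
}

# Vectorised Gaussian naive-Bayes posterior from an e1071 fit. Equivalent to
# predict.naiveBayes on all-numeric input (which loops over rows), with the
# same sd floor semantics; ties go to the first (lower) class level.
nb_predict_gaussian <- function(fit, x) {
  log_post <- matrix(log(fit$apriori), nrow(x), 2, byrow = TRUE)
  for (j in seq_len(ncol(x))) {
    tab <- fit$tables[[colnames(x)[j]]]   # 2 x 2: rows = classes, mean/sd
    sds <- pmax(tab[, 2], 1e-9)
    log_post[, 1] <- log_post[, 1] + stats::dnorm(x[, j], tab[1, 1], sds[1], log = TRUE)
    log_post[, 2] <- log_post[, 2] + stats::dnorm(x[, j], tab[2, 1], sds[2], log = TRUE)
  }
  as.integer(log_post[, 2] > log_post[, 1])
}

# Matrix-level prediction on already mask-subset columns.
predict_learner_x <- function(object, x) {
  if (nrow(x) == 0) return(integer(0))
  if (!is.null(object$center)) {
    x <- scale(x, center = object$center, scale = object$scale)
  }
  spec <- object$spec
  out <- switch(
    spec$kind,
    knn = {
      pred <- class::knn(object$model$x, x, factor(object$model$y),
                         k = spec$params$k, prob = TRUE, use.all = TRUE)
      votes <- attr(pred, "prob")
      lab <- as.integer(as.character(pred))
      lab[abs(votes - 0.5) < 1e-12] <- 0L   # tie: lower label wins
      lab
    },
    svm = svm_predict_decision(object$model, x),
    lda = {
      if (object$fallback) {
        rep(object$majority, nrow(x))
      } else {
        keep <- object$model$keep
        as.integer(as.character(
          predict(object$model$fit, x[, keep, drop = FALSE])$class
        ))
      }
    },
    bayes = {
      if (object$fallback) {
        rep(object$majority, nrow(x))
      } else {
        nb_predict_gaussian(object$model$fit,
                            x[, object$model$keep, drop = FALSE])
      }
    },
    tree = as.integer(as.character(
      predict(object$model, as.data.frame(x), type = "class")
    )),
    mlp = as.integer(predict(object$model, x) > 0.5)
  )
  as.integer(out)
}
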