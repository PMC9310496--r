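#' Configuration of the genetic search
#'
#' Bundles every tunable of the evolutionary optimisation. Defaults follow
#' the reference parameterisation: 100 generations, population 50, elite /
#' crossover / mutation shares 0.10 / 0.60 / 0.30, roulette-wheel selection
#' with power 2, 10-fold cross-validated fitness. The `"prose"` preset
#' switches the generation shares to 0.10 / 0.50 / 0.40, the alternative
#' triple in circulation for this method.
#'
#' @param iterations Number of generations (termination is iteration count
#'   only).
#' @param population_size Chromosomes per generation (>= 2).
#' @param p_elite,p_crossover,p_mutation Generation-composition shares; must
#'   sum to 1.
#' @param selection_power Exponent applied to fitness in roulette selection.
#' @param k_folds Cross-validation folds for fitness evaluation.
#' @param weights A [cost_weights()] vector scalarising err / FPR / FRR.
#' @param threshold Ensemble decision threshold.
#' @param bit_flip_rate Per-bit flip probability of the mutation operator;
#'   `NULL` (default) resolves to `1/N` at run time, the classical rate that
#'   flips one bit per feature row on average.
#' @param weight_sd Standard deviation of the Gaussian perturbation of
#'   learner weights under mutation.
#' @param fold_aggregation `"mean"` (average of per-fold costs, default) or
#'   `"pooled"` (confusion counts summed over folds, cost computed once).
#' @param optimize_weights If `FALSE` the learner weights are frozen at
#'   uniform and only feature masks evolve.
#' @param epsilon Cost floor before inversion to fitness (fitness of a
#'   zero-cost chromosome is `1 / epsilon`).
#' @param preset `"table1"` (default shares) or `"prose"`.
#' @return A `ga_config` list.
#' @export
ga_config <- function(iterations = 100, population_size = 50,
                      p_elite = 0.10, p_crossover = 0.60, p_mutation = 0.30,
                      selection_power = 2, k_folds = 10,
                      weights = cost_weights(), threshold = 0.5,
                      bit_flip_rate = NULL, weight_sd = 0.10,
                      fold_aggregation = c("mean", "pooled"),
                      optimize_weights = TRUE, epsilon = 1e-6,
                      preset = NULL) {
  if (!is.null(preset)) {
    shares <- switch(
      preset,
      table1 = c(0.10, 0.60, 0.30),
      prose = c(0.10, 0.50, 0.40),
      abort("Unknown preset; use \"table1\" or \"prose\".",
            class = "efsemble_error_config")
    )
    p_elite <- shares[1]; p_crossover <- shares[2]; p_mutation <- shares[3]
  }
  if (abs(p_elite + p_crossover + p_mutation - 1) > 1e-8) {
    abort("p_elite + p_crossover + p_mutation must equal 1.",
          class = "efsemble_error_config")
  }
  if (iterations < 1 || population_size < 2 || k_folds < 2) {
    abort("Need iterations >= 1, population_size >= 2, k_folds >= 2.",
          class = "efsemble_error_config")
  }
  structure(
    list(iterations = iterations, population_size = population_size,
         p_elite = p_elite, p_crossover = p_crossover,
         p_mutation = p_mutation, selection_power = selection_power,
         k_folds = k_folds, weights = weights, threshold = threshold,
         bit_flip_rate = bit_flip_rate, weight_sd = weight_sd,
         fold_aggregation = match.arg(fold_aggregation),
         optimize_weights = optimize_weights, epsilon = epsilon),
    class = "ga_config"
  )
}

#' Stratified cross-validation folds
#'
#' Assigns each case to one of `k` folds with class proportions preserved,
#' so every training and test part of an imbalanced cohort contains both
#' classes.
#'
#' @param y 0/1 label vector.
#' @param k Number of folds; each class must have at least `k` members.
#' @return Integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(y, k) {
  if (min(table(y)) < k) {
    abort("Each class needs at least `k` members for stratified folds.",
          class = "efsemble_error_stratification")
  }
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Draw a random initial population
#'
#' Learner weights uniform on `[0, 1]`, feature bits Bernoulli(1/2), all
#' candidates repaired to validity.
#'
#' @param config A [ga_config()].
#' @param R Number of base learners.
#' @param N Number of features (>= 1).
#' @param learners,features Optional dimension names.
#' @return List of `population_size` chromosomes.
#' @export
init_population <- function(config, R, N, learners = NULL, features = NULL) {
  if (N < 1) abort("Need at least one feature.", class = "efsemble_error_config")
  lapply(seq_len(config$population_size), function(i) {
    el <- if (config$optimize_weights) runif(R) else rep(1 / R, R)
    fs <- matrix(runif(R * N) < 0.5, nrow = R,
                 dimnames = list(learners, features))
    validate_chromosome(list(el = el, fs = fs), mode = "repair")
  })
}

#' Roulette-wheel parent selection
#'
#' Draws parent indices with probability proportional to
#' `fitness^selection_power`; with power 2 the canonical quadratic wheel.
#'
#' @param fitness Positive finite fitness values, one per chromosome.
#' @param power Selection exponent.
#' @param n Number of draws.
#' @return Integer vector of `n` selected indices.
#' @export
roulette_select <- function(fitness, power = 2, n = 1) {
  if (length(fitness) == 0) {
    abort("Empty population.", class = "efsemble_error_value")
  }
  if (any(!is.finite(fitness) | fitness <= 0)) {
    abort("Fitness values must be positive and finite.",
          class = "efsemble_error_value")
  }
  w <- fitness^power
  sample.int(length(fitness), n, replace = TRUE, prob = w)
}

#' Uniform crossover of two chromosomes
#'
#' Feature bits mix uniformly (each child bit from one parent, the siblings
#' complementary); learner weights blend convexly with a shared random
#' coefficient `beta ~ U(0, 1)`: `el1' = beta el1 + (1 - beta) el2` and
#' symmetrically. Children are repaired to validity.
#'
#' @param p1,p2 Parent chromosomes with matching dimensions.
#' @param optimize_weights If `FALSE` children keep their parents' weights.
#' @return List of two chromosomes.
#' @export
crossover_chromosomes <- function(p1, p2, optimize_weights = TRUE) {
  if (!all(dim(p1$fs) == dim(p2$fs))) {
    abort("Parent dimensions differ.", class = "efsemble_error_value")
  }
  pick <- matrix(runif(length(p1$fs)) < 0.5, nrow = nrow(p1$fs))
  fs1 <- ifelse(pick, p1$fs, p2$fs)
  fs2 <- ifelse(pick, p2$fs, p1$fs)
  dimnames(fs1) <- dimnames(fs2) <- dimnames(p1$fs)
  if (optimize_weights) {
    beta <- runif(1)
    el1 <- beta * p1$el + (1 - beta) * p2$el
    el2 <- (1 - beta) * p1$el + beta * p2$el
  } else {
    el1 <- p1$el; el2 <- p2$el
  }
  list(
    validate_chromosome(list(el = el1, fs = fs1), mode = "repair"),
    validate_chromosome(list(el = el2, fs = fs2), mode = "repair")
  )
}

#' Mutate a chromosome
#'
#' Each feature bit flips independently with probability `bit_flip_rate`;
#' each learner weight is perturbed by Gaussian noise of standard deviation
#' `weight_sd` and clipped to `[0, 1]`. The result is repaired to validity,
#' so mutation never leaves the feasible space.
#'
#' @param c A chromosome.
#' @param bit_flip_rate Per-bit flip probability.
#' @param weight_sd Weight perturbation scale.
#' @param optimize_weights If `FALSE` weights are left untouched.
#' @return A valid chromosome.
#' @export
mutate_chromosome <- function(c, bit_flip_rate = 0.02, weight_sd = 0.10,
                              optimize_weights = TRUE) {
  flip <- matrix(runif(length(c$fs)) < bit_flip_rate, nrow = nrow(c$fs))
  fs <- xor(c$fs, flip)
  dimnames(fs) <- dimnames(c$fs)
  el <- c$el
  if (optimize_weights && weight_sd > 0) {
    el <- pmin(pmax(el + rnorm(length(el), 0, weight_sd), 0), 1)
  }
  validate_chromosome(list(el = el, fs = fs), mode = "repair")
}

# Per-(learner, mask) fold-prediction cache: base-learner votes do not
# depend on the weight vector, so they are shared across chromosomes.
learner_fold_votes <- function(j, mask, roster, x, y, fold_idx, cache) {
  key <- paste0(j, ":", paste0(as.integer(mask), collapse = ""))
  hit <- cache$votes[[key]]
  if (!is.null(hit)) return(hit)
  spec <- roster[[j]]
  votes <- lapply(fold_idx, function(f) {
    fit <- fit_learner_xy(spec, x[f$train, , drop = FALSE], y[f$train], mask)
    predict_learner_x(fit, x[f$test, mask, drop = FALSE])
  })
  cache$votes[[key]] <- votes
  cache$misses <- cache$misses + 1L
  votes
}

#' Cross-validated cost of a chromosome
#'
#' The fitness evaluation: for each fold, the R base learners are fitted on
#' the training part under the chromosome's feature masks, the weighted vote
#' is applied to the test part, and the weighted err/FPR/FRR cost is
#' computed. The chromosome's cost is the mean of per-fold costs (or the
#' cost of pooled counts, per `config$fold_aggregation`); its fitness is
#' `1 / max(cost, epsilon)`.
#'
#' @param chrom A [chromosome()] whose `fs` has one row per roster entry.
#' @param data Feature tibble with 0/1 label column.
#' @param config A [ga_config()].
#' @param roster List of [learner_spec()]s, default [ensemble_roster()].
#' @param label Label column name.
#' @param folds Optional precomputed fold assignment from
#'   [stratified_folds()]; drawn fresh otherwise.
#' @return A list with `cost`, `fitness`, `fold_costs`, and `counts` (pooled
#'   confusion tibble).
#' @export
evaluate_chromosome <- function(chrom, data, config = ga_config(),
                                roster = ensemble_roster(), label = "class",
                                folds = NULL) {
  fm <- feature_matrix(data, label)
  if (is.null(folds)) folds <- stratified_folds(fm$y, config$k_folds)
  fold_idx <- split_folds(folds)
  cache <- new_vote_cache()
  eval_chromosome_xy(chrom, fm$x, fm$y, fold_idx, roster, config, cache)
}

split_folds <- function(folds) {
  lapply(sort(unique(folds)), function(k) {
    list(train = which(folds != k), test = which(folds == k))
  })
}

new_vote_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$votes <- list()
  e$misses <- 0L
  e
}

#' Create a reusable vote cache
#'
#' Base-learner fold predictions depend only on the learner, its feature
#' mask, the data and the folds — not on the chromosome's weights. A shared
#' cache lets repeated [ga_fit()] runs on identical data and folds skip
#' re-training; results are unchanged.
#'
#' @return An environment to pass as the `cache` argument of [ga_fit()].
#' @export
vote_cache <- function() new_vote_cache()

eval_chromosome_xy <- function(chrom, x, y, fold_idx, roster, config, cache) {
  R <- nrow(chrom$fs)
  w <- config$weights
  el_sum <- sum(chrom$el)
  all_votes <- lapply(seq_len(R), function(j) {
    learner_fold_votes(j, chrom$fs[j, ], roster, x, y, fold_idx, cache)
  })
  # plain-arithmetic confusion tallies (hot path; the tibble interface in
  # the metrics module is cross-checked against this in the tests)
  cells <- matrix(0, length(fold_idx), 4)   # ta, fr, tr, fa per fold
  for (f in seq_along(fold_idx)) {
    n_test <- length(fold_idx[[f]]$test)
    score <- numeric(n_test)
    for (j in seq_len(R)) score <- score + chrom$el[j] * all_votes[[j]][[f]]
    pred <- as.integer(score / el_sum >= config$threshold)
    truth <- y[fold_idx[[f]]$test]
    ta <- sum(truth == 0 & pred == 0)
    fr <- sum(truth == 0 & pred == 1)
    tr <- sum(truth == 1 & pred == 1)
    cells[f, ] <- c(ta, fr, tr, n_test - ta - fr - tr)
  }
  cost_of <- function(ta, fr, tr, fa) {
    err <- (fr + fa) / (ta + fr + tr + fa)
    unname(w["err"] * err + w["fpr"] * fa / (tr + fa) +
           w["frr"] * fr / (ta + fr))
  }
  fold_costs <- vapply(seq_along(fold_idx), function(f) {
    cost_of(cells[f, 1], cells[f, 2], cells[f, 3], cells[f, 4])
  }, numeric(1))
  pooled_cells <- colSums(cells)
  pooled <- as_confusion_counts(pooled_cells[1], pooled_cells[2],
                                pooled_cells[3], pooled_cells[4])
  cost <- if (config$fold_aggregation == "mean") {
    mean(fold_costs)
  } else {
    cost_of(pooled_cells[1], pooled_cells[2],
            pooled_cells[3], pooled_cells[4])
  }
  list(cost = cost, fitness = 1 / max(cost, config$epsilon),
       fold_costs = fold_costs, counts = pooled)
}

#' Exhaustive search over feature masks (tiny instances)
#'
#' Enumerates every combination of nonempty per-learner feature masks at
#' uniform learner weights and evaluates each with the same cross-validated
#' cost as the genetic search. Only feasible for tiny instances (the space
#' has `(2^N - 1)^R` points); used to certify how close the stochastic
#' search gets to the true optimum.
#'
#' @inheritParams evaluate_chromosome
#' @param folds Fold assignment shared with the runs being certified.
#' @return A list with `best_cost`, `best_masks` (R x N logical matrix) and
#'   `n_evaluated`.
#' @export
exhaustive_mask_search <- function(data, config = ga_config(),
                                   roster = ensemble_roster(),
                                   label = "class", folds = NULL) {
  fm <- feature_matrix(data, label)
  R <- length(roster)
  N <- ncol(fm$x)
  if ((2^N - 1)^R > 2e5) {
    abort("Search space too large to enumerate.",
          class = "efsemble_error_config")
  }
  if (is.null(folds)) folds <- stratified_folds(fm$y, config$k_folds)
  fold_idx <- split_folds(folds)
  cache <- new_vote_cache()
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), N)))[-1, ,
                                                                drop = FALSE]
  el <- rep(1 / R, R)
  combo <- rep(1L, R)
  best <- list(cost = Inf, masks = NULL)
  n_eval <- 0L
  repeat {
    fs <- masks[combo, , drop = FALSE]
    dimnames(fs) <- list(names(roster), fm$features)
    rec <- eval_chromosome_xy(structure(list(el = el, fs = fs),
                                        class = "chromosome"),
                              fm$x, fm$y, fold_idx, roster, config, cache)
    n_eval <- n_eval + 1L
    if (rec$cost < best$cost) best <- list(cost = rec$cost, masks = fs)
    j <- 1L
    while (j <= R) {
      combo[j] <- combo[j] + 1L
      if (combo[j] <= nrow(masks)) break
      combo[j] <- 1L
      j <- j + 1L
    }
    if (j > R) break
  }
  list(best_cost = best$cost, best_masks = best$masks, n_evaluated = n_eval)
}

#' Run the genetic search
#'
#' Evolves a population of two-layer chromosomes for exactly
#' `config$iterations` generations. Each generation keeps the `p_elite`
#' best chromosomes unchanged, fills `p_crossover` of the population with
#' children of roulette-selected parents and the remainder with mutants of
#' roulette-selected parents. The best chromosome ever evaluated is
#' returned; elitism makes the per-generation best cost non-increasing.
#'
#' @param data Feature tibble with a 0/1 label column.
#' @param config A [ga_config()].
#' @param roster Base-learner roster, default [ensemble_roster()]; the
#'   chromosome's R equals its length.
#' @param label Label column name.
#' @param seed Integer seed; the full run is reproducible from
#'   `(seed, config, data)`.
#' @param folds Optional fold assignment from [stratified_folds()]; fixing it
#'   lets several runs (or an external baseline) share identical folds.
#' @param cache Optional vote cache environment shared between runs; only
#'   valid when `data`, `roster` and `folds` are identical across the runs
#'   sharing it. Results are unchanged, re-training is skipped.
#' @return A `ga_fit` object: `best_chromosome`, `best_cost`, `best_counts`,
#'   `trajectory` (tibble of per-generation best/mean cost), `folds`,
#'   `config`, `seed`, `n_evaluations`.
#' @export
ga_fit <- function(data, config = ga_config(), roster = ensemble_roster(),
                   label = "class", seed = 1, folds = NULL, cache = NULL) {
  set.seed(seed)
  fm <- feature_matrix(data, label)
  R <- length(roster)
  N <- ncol(fm$x)
  if (is.null(folds)) folds <- stratified_folds(fm$y, config$k_folds)
  fold_idx <- split_folds(folds)
  if (is.null(cache)) cache <- new_vote_cache()
  n_eval <- 0L

  eval_one <- function(chrom) {
    n_eval <<- n_eval + 1L
    eval_chromosome_xy(chrom, fm$x, fm$y, fold_idx, roster, config, cache)
  }

  bit_rate <- config$bit_flip_rate %||% (1 / N)
  pop <- init_population(config, R, N, learners = names(roster),
                         features = fm$features)
  recs <- lapply(pop, eval_one)
  costs <- vapply(recs, `[[`, numeric(1), "cost")

  best_i <- which.min(costs)
  best <- list(chromosome = pop[[best_i]], record = recs[[best_i]])

  pop_size <- config$population_size
  n_elite <- max(1L, round(config$p_elite * pop_size))
  n_cross <- round(config$p_crossover * pop_size)
  n_mut <- pop_size - n_elite - n_cross

  trajectory <- vector("list", config$iterations)
  for (gen in seq_len(config$iterations)) {
    ord <- order(costs)
    fitness <- vapply(recs, `[[`, numeric(1), "fitness")

    elite_idx <- ord[seq_len(n_elite)]
    new_pop <- pop[elite_idx]
    new_recs <- recs[elite_idx]

    if (n_cross > 0) {
      n_pairs <- ceiling(n_cross / 2)
      parents <- roulette_select(fitness, config$selection_power, 2 * n_pairs)
      children <- list()
      for (p in seq_len(n_pairs)) {
        pair <- crossover_chromosomes(pop[[parents[2 * p - 1]]],
                                      pop[[parents[2 * p]]],
                                      config$optimize_weights)
        children <- c(children, pair)
      }
      new_pop <- c(new_pop, children[seq_len(n_cross)])
    }
    if (n_mut > 0) {
      donors <- roulette_select(fitness, config$selection_power, n_mut)
      mutants <- lapply(pop[donors], mutate_chromosome,
                        bit_flip_rate = bit_rate,
                        weight_sd = config$weight_sd,
                        optimize_weights = config$optimize_weights)
      new_pop <- c(new_pop, mutants)
    }

    fresh <- lapply(new_pop[-seq_len(n_elite)], eval_one)
    pop <- new_pop
    recs <- c(new_recs, fresh)
    costs <- vapply(recs, `[[`, numeric(1), "cost")

    gen_best <- which.min(costs)
    if (costs[gen_best] < best$record$cost) {
      best <- list(chromosome = pop[[gen_best]], record = recs[[gen_best]])
    }
    trajectory[[gen]] <- tibble(
      generation = gen,
      best_cost = costs[gen_best],
      mean_cost = mean(costs)
    )
  }

  structure(
    list(
      best_chromosome = best$chromosome,
      best_cost = best$record$cost,
      best_fitness = best$record$fitness,
      best_counts = best$record$counts,
      best_fold_costs = best$record$fold_costs,
      trajectory = dplyr::bind_rows(trajectory),
      folds = folds,
      config = config,
      roster = roster,
      label = label,
      seed = seed,
      n_evaluations = n_eval,
      cache_misses = cache$misses
    ),
    class = "ga_fit"
  )
}

#' @export
print.ga_fit <- function(x, ...) {
  cat("<ga_fit>\n")
  cat(sprintf("  %d generations, population %d, %d-fold CV, seed %d\n",
              x$config$iterations, x$config$population_size,
              x$config$k_folds, x$seed))
  cat(sprintf("  best cost %.4f (fitness %.2f), %d evaluations\n",
              x$best_cost, x$best_fitness, x$n_evaluations))
  cat("  best chromosome: "); print(x$best_chromosome)
  invisible(x)
}

#' Tidy the search trajectory
#'
#' @param x A `ga_fit`.
#' @param ... Unused.
#' @return Tibble with `generation`, `best_cost`, `mean_cost`.
#' @exportS3Method generics::tidy
tidy.ga_fit <- function(x, ...) x$trajectory

#' One-row summary of a GA run
#'
#' @param x A `ga_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the best cost and its rate decomposition.
#' @exportS3Method generics::glance
glance.ga_fit <- function(x, ...) {
  rates <- classification_rates(x$best_counts)
  tibble(
    best_cost = x$best_cost,
    fpr = rates$fpr, frr = rates$frr, accuracy = rates$accuracy,
    generations = x$config$iterations,
    population_size = x$config$population_size,
    k_folds = x$config$k_folds,
    n_evaluations = x$n_evaluations,
    seed = x$seed
  )
}

#' Plot the best/mean cost trajectory of a GA run
#'
#' @param object A `ga_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ga_fit <- function(object, ...) {
  traj <- tidyr::pivot_longer(object$trajectory,
                              c("best_cost", "mean_cost"),
                              names_to = "series", values_to = "cost")
  ggplot2::ggplot(traj, ggplot2::aes(.data$generation, .data$cost,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(best_cost = "#00441b", mean_cost = "#74c476"),
      labels = c(best_cost = "best", mean_cost = "population mean")
    ) +
    ggplot2::labs(x = "generation", y = "weighted err/FPR/FRR cost",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
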