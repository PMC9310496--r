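test_that("generation shares must sum to one; presets supply both triples", {
  expect_error(ga_config(p_elite = 0.2, p_crossover = 0.2, p_mutation = 0.2),
               class = "efsemble_error_config")
  cfg <- ga_config(preset = "table1")
  expect_equal(c(cfg$p_elite, cfg$p_crossover, cfg$p_mutation),
               c(0.10, 0.60, 0.30))
  cfg <- ga_config(preset = "prose")
  expect_equal(c(cfg$p_elite, cfg$p_crossover, cfg$p_mutation),
               c(0.10, 0.50, 0.40))
  expect_error(ga_config(preset = "nope"), class = "efsemble_error_config")
  expect_error(ga_config(iterations = 0), class = "efsemble_error_config")
})

test_that("stratified folds preserve both classes in every part", {
  set.seed(5)
  y <- c(rep(1L, 74), rep(0L, 23))
  fold <- stratified_folds(y, 10)
  for (k in 1:10) {
    expect_setequal(unique(y[fold == k]), c(0L, 1L))
    expect_setequal(unique(y[fold != k]), c(0L, 1L))
  }
  expect_error(stratified_folds(c(1, 1, 1, 0), 3),
               class = "efsemble_error_stratification")
})

test_that("initial populations are valid, reproducible, and repair forced rows", {
  cfg <- ga_config(population_size = 50, k_folds = 2)
  set.seed(9)
  pop <- init_population(cfg, R = 5, N = 30)
  expect_length(pop, 50)
  for (ch in pop) {
    expect_true(all(rowSums(ch$fs) >= 1))
    expect_true(all(ch$el >= 0 & ch$el <= 1))
  }
  set.seed(9)
  pop2 <- init_population(cfg, R = 5, N = 30)
  expect_identical(pop, pop2)

  set.seed(9)
  narrow <- init_population(cfg, R = 3, N = 1)
  for (ch in narrow) expect_equal(unname(ch$fs[, 1]), rep(TRUE, 3))
  expect_error(init_population(cfg, R = 2, N = 0),
               class = "efsemble_error_config")
})

test_that("roulette selection follows fitness^2 proportions", {
  # costs (1, 2) -> fitness (1, 0.5) -> squared weights (1, 0.25)
  set.seed(10)
  draws <- roulette_select(c(1, 0.5), power = 2, n = 20000)
  expect_equal(mean(draws == 1), 0.8, tolerance = 0.02)
  # equal costs: symmetric selection
  draws <- roulette_select(c(2, 2), power = 2, n = 20000)
  expect_equal(mean(draws == 1), 0.5, tolerance = 0.02)
  # single record is always chosen
  expect_equal(unique(roulette_select(5, n = 100)), 1L)
  expect_error(roulette_select(numeric(0)), class = "efsemble_error_value")
  expect_error(roulette_select(c(1, Inf)), class = "efsemble_error_value")
})

test_that("crossover mixes bits within parental support and blends weights", {
  set.seed(11)
  p1 <- validate_chromosome(
    list(el = c(1, 0), fs = rbind(rep(TRUE, 6), rep(c(TRUE, FALSE), 3))),
    "repair"
  )
  p2 <- validate_chromosome(
    list(el = c(0, 1), fs = rbind(rep(TRUE, 6), rep(c(FALSE, TRUE), 3))),
    "repair"
  )
  kids <- crossover_chromosomes(p1, p2)
  for (kid in kids) {
    # each bit comes from one of the parents
    expect_true(all(kid$fs[2, ] %in% c(p1$fs[2, ], p2$fs[2, ])))
    # convex blend: weights sum to the blended total
    expect_equal(sum(kid$el), 1)
  }
  # identical parents reproduce themselves
  same <- crossover_chromosomes(p1, p1)
  expect_equal(same[[1]]$fs, p1$fs)
  expect_equal(same[[1]]$el, p1$el)
  expect_error(
    crossover_chromosomes(p1, validate_chromosome(
      list(el = c(1, 1), fs = matrix(TRUE, 2, 3)), "repair"
    )),
    class = "efsemble_error_value"
  )
})

test_that("mutation is the identity at zero rates and repairs forced zeros", {
  ch <- validate_chromosome(
    list(el = c(0.4, 0.6), fs = matrix(TRUE, 2, 5)), "repair"
  )
  expect_equal(mutate_chromosome(ch, bit_flip_rate = 0, weight_sd = 0), ch)

  set.seed(12)
  one_row <- validate_chromosome(
    list(el = 1, fs = matrix(TRUE, 1, 5)), "repair"
  )
  flipped <- mutate_chromosome(one_row, bit_flip_rate = 1, weight_sd = 0)
  expect_equal(sum(flipped$fs), 1)  # all bits flipped off, repair sets one
})

test_that("expected flips per mutation match the binomial mean", {
  set.seed(13)
  ch <- validate_chromosome(
    list(el = runif(5), fs = matrix(runif(250) < 0.5, 5, 50)), "repair"
  )
  flips <- replicate(4000, {
    m <- mutate_chromosome(ch, bit_flip_rate = 0.02, weight_sd = 0)
    sum(xor(m$fs, ch$fs))
  })
  # 250 bits at rate 0.02: mean 5 (repair perturbs this only negligibly)
  expect_equal(mean(flips), 5, tolerance = 0.1)
})

test_that("k-fold evaluation matches a hand-rolled fold loop", {
  tab <- quick_cohort(n_pos = 12, n_neg = 8, n_informative = 2, n_noise = 2,
                      effect_size = 1.5, seed = 51)
  ros <- ensemble_roster()
  cfg <- ga_config(k_folds = 2, population_size = 2)
  set.seed(14)
  folds <- stratified_folds(tab$class, 2)
  set.seed(15)
  fs <- matrix(runif(5 * 4) < 0.7, 5, 4,
               dimnames = list(names(ros), setdiff(names(tab), "class")))
  fs[rowSums(fs) == 0, 1] <- TRUE
  ch <- chromosome(runif(5), fs)

  rec <- evaluate_chromosome(ch, tab, cfg, folds = folds)

  # oracle: explicit loop over the two folds with hand arithmetic
  fold_costs <- vapply(1:2, function(k) {
    train <- tab[folds != k, ]
    test <- tab[folds == k, ]
    votes <- vapply(seq_along(ros), function(j) {
      predict(fit_learner(ros[[j]], train, mask = ch$fs[j, ]), test)
    }, integer(nrow(test)))
    score <- as.numeric(votes %*% ch$el) / sum(ch$el)
    pred <- as.integer(score >= 0.5)
    truth <- test$class
    fa <- sum(truth == 1 & pred == 0)   # lymphedema accepted as healthy
    fr <- sum(truth == 0 & pred == 1)   # healthy rejected
    fpr <- fa / sum(truth == 1)
    frr <- fr / sum(truth == 0)
    err <- mean(pred != truth)
    (err + fpr + frr) / 3
  }, numeric(1))
  expect_equal(rec$fold_costs, fold_costs)
  expect_equal(rec$cost, mean(fold_costs))
  expect_equal(rec$fitness, 1 / max(rec$cost, cfg$epsilon))
})

test_that("a separable cohort drives the cost to zero and fitness to the cap", {
  tab <- make_fixture("separable")
  ros <- ensemble_roster()
  full <- chromosome(
    rep(1, 5),
    matrix(TRUE, 5, 3, dimnames = list(names(ros),
                                       setdiff(names(tab), "class")))
  )
  set.seed(16)
  rec <- evaluate_chromosome(full, tab, ga_config(k_folds = 3))
  expect_equal(rec$cost, 0)
  expect_equal(rec$fitness, 1e6)
})

test_that("error-only weights reduce the cost to the mean fold error", {
  tab <- quick_cohort(n_pos = 30, n_neg = 20, seed = 52)
  ros <- ensemble_roster()
  full <- chromosome(
    rep(1, 5),
    matrix(TRUE, 5, 4, dimnames = list(names(ros),
                                       setdiff(names(tab), "class")))
  )
  cfg <- ga_config(k_folds = 2, weights = cost_weights(1, 0, 0))
  set.seed(17)
  folds <- stratified_folds(tab$class, 2)
  rec <- evaluate_chromosome(full, tab, cfg, folds = folds)
  errs <- vapply(1:2, function(k) {
    train <- tab[folds != k, ]
    test <- tab[folds == k, ]
    votes <- vapply(seq_along(ros), function(j) {
      predict(fit_learner(ros[[j]], train, mask = rep(TRUE, 4)), test)
    }, integer(nrow(test)))
    pred <- as.integer(rowMeans(votes) >= 0.5)
    mean(pred != test$class)
  }, numeric(1))
  expect_equal(rec$cost, mean(errs))
})

test_that("a one-generation run preserves population size and logs one point", {
  tab <- quick_cohort(seed = 53)
  run <- ga_fit(tab, ga_config(iterations = 1, population_size = 4,
                               k_folds = 2), seed = 18)
  expect_equal(nrow(run$trajectory), 1)
  expect_s3_class(run$best_chromosome, "chromosome")
})

test_that("elitism makes the best-cost trajectory non-increasing", {
  tab <- quick_cohort(n_pos = 45, n_neg = 35, n_informative = 2,
                      n_noise = 4, effect_size = 0.8, seed = 54)
  run <- ga_fit(tab, ga_config(iterations = 20, population_size = 8,
                               k_folds = 3), seed = 19)
  expect_equal(nrow(run$trajectory), 20)
  expect_true(all(diff(run$trajectory$best_cost) <= 1e-12))
  expect_equal(run$best_cost, min(run$trajectory$best_cost))
})

test_that("runs are bitwise reproducible from (seed, config, table)", {
  tab <- quick_cohort(seed = 55)
  cfg <- quick_ga_config()
  r1 <- ga_fit(tab, cfg, seed = 20)
  r2 <- ga_fit(tab, cfg, seed = 20)
  expect_identical(r1$best_chromosome, r2$best_chromosome)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$folds, r2$folds)
  r3 <- ga_fit(tab, cfg, seed = 21)
  expect_false(identical(r1$trajectory, r3$trajectory))
})

test_that("tidy, glance and autoplot expose the run", {
  tab <- quick_cohort(seed = 56)
  run <- ga_fit(tab, quick_ga_config(), seed = 22)
  expect_equal(names(tidy(run)), c("generation", "best_cost", "mean_cost"))
  gl <- glance(run)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$best_cost, run$best_cost)
  expect_s3_class(autoplot(run), "ggplot")
})
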