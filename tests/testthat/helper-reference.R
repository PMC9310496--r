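# Reference single-classifier benchmark: confusion matrices over class
# totals 690 (target/healthy) and 740 (lymphedema) with the rate values
# they imply at 4-decimal display precision.
reference_benchmark <- function() {
  tibble::tribble(
    ~learner,         ~ta,  ~fr,  ~tr,  ~fa,  ~fpr,   ~frr,   ~accuracy,
    "svm_linear",      547,  143,  555,  185,  0.2500, 0.2072, 0.7706,
    "svm_rbf",         637,   53,  630,  110,  0.1486, 0.0768, 0.8860,
    "svm_polynomial",  668,   22,  565,  175,  0.2365, 0.0319, 0.8622,
    "lda",             548,  142,  536,  204,  0.2757, 0.2058, 0.7580,
    "knn",             619,   71,  447,  293,  0.3959, 0.1029, 0.7455,
    "bayes",           570,  120,  406,  334,  0.4514, 0.1739, 0.6825,
    "c5",              552,  138,  620,  120,  0.1622, 0.2000, 0.8196,
    "mlp",             501,  189,  576,  164,  0.2216, 0.2739, 0.7531
  )
}

# A small feature table with a fresh RNG stream, for tests that need
# throwaway cohorts without disturbing fixture seeds.
quick_cohort <- function(n_pos = 60, n_neg = 40, n_informative = 2,
                         n_noise = 2, effect_size = 2, seed = 99) {
  simulate_feature_table(n_pos, n_neg, n_informative, n_noise,
                         effect_size, seed)
}

# GA configuration small enough for unit tests.
quick_ga_config <- function(...) {
  ga_config(iterations = 3, population_size = 6, k_folds = 3, ...)
}
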