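test_that("stratified folds partition the samples with balanced classes", {
  y <- rep(c(1L, 0L), each = 10)                 # 10/10, 10 folds
  folds <- stratified_folds(y, 10, seed = 1)
  tests <- lapply(folds, `[[`, "test")
  expect_identical(sort(unlist(tests)), 1:20)    # covering, disjoint
  for (f in folds) {
    expect_identical(sum(y[f$test]), 1L)         # exactly one of each class
    expect_identical(length(f$test), 2L)
    expect_identical(sort(c(f$train, f$test)), 1:20)
  }
})

test_that("the 64/12 imbalance still puts minority samples in every fold", {
  y <- rep(c(0L, 1L), c(64, 12))
  folds <- stratified_folds(y, 10, seed = 3)
  minority <- vapply(folds, function(f) sum(y[f$test]), integer(1))
  majority <- vapply(folds, function(f) sum(y[f$test] == 0L), integer(1))
  expect_true(all(minority >= 1L))
  expect_true(all(minority %in% 1:2))            # within 1 of 12/10
  expect_true(all(majority %in% 6:7))            # within 1 of 64/10
  expect_identical(sort(unlist(lapply(folds, `[[`, "test"))), 1:76)
})

test_that("fold drawing is seeded and guards against tiny classes", {
  y <- rep(c(0L, 1L), c(30, 20))
  expect_identical(stratified_folds(y, 5, seed = 7),
                   stratified_folds(y, 5, seed = 7))
  expect_error(stratified_folds(rep(c(0L, 1L), c(40, 4)), 10, seed = 1),
               "cannot stratify")
})

test_that("baselines fit, predict 0/1, and behave sanely", {
  set.seed(12)
  X <- matrix(rnorm(5 * 40), 5, 40,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:40)))
  y <- as.integer(X[1, ] > 0)
  X[1, ] <- X[1, ] + ifelse(y == 1, 3, -3)       # cleanly separable

  for (nm in c("DT", "NB", "KNN", "SVM", "RF")) {
    fit <- fit_baseline(nm, X, y, seed = 5)
    pred <- predict(fit, X)
    expect_true(all(pred %in% 0:1))
    expect_gte(percent_correct(confusion(pred, y)), 95)
  }
  expect_error(fit_baseline("LDA", X, y), "arg")

  # a memorizing decision tree is perfect on a tiny separable toy
  toy_X <- matrix(c(0, 0, 0, 1, 5, 0, 5, 1), 2, 4,
                  dimnames = list(c("a", "b"), paste0("s", 1:4)))
  toy_y <- c(0L, 0L, 1L, 1L)
  dt <- fit_baseline("DT", toy_X, toy_y)
  expect_identical(predict(dt, toy_X), toy_y)

  # knn k=3: a point surrounded by 3 same-class neighbours takes that class
  knn_X <- matrix(c(0, 0, 0.1, 0, -0.1, 0, 0, 0.1, 9, 9, 9.1, 9), 2, 6,
                  dimnames = list(c("a", "b"), paste0("s", 1:6)))
  knn_y <- c(1L, 1L, 1L, 1L, 0L, 0L)
  knn <- fit_baseline("KNN", knn_X[, -1], knn_y[-1], knn_k = 3)
  expect_identical(predict(knn, knn_X[, 1, drop = FALSE]), 1L)
})

test_that("naive Bayes predictions swap when the classes are swapped", {
  set.seed(33)
  X <- matrix(rnorm(4 * 60), 4, 60,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:60)))
  y <- as.integer(X[2, ] + rnorm(60, sd = 0.3) > 0)
  f1 <- fit_baseline("NB", X, y)
  f2 <- fit_baseline("NB", X, 1L - y)
  expect_identical(predict(f1, X), 1L - predict(f2, X))
})

test_that("summaries aggregate with sample standard deviation", {
  rec <- data.frame(classifier = "GP", rp_dim = "50", rep = 1, fold = 1:2,
                    train_mcc100 = c(1, 1), train_pct = c(1, 1),
                    test_balanced = c(80, 90))
  s <- summarize_records(rec)
  row <- s[s$metric == "test_balanced", ]
  expect_equal(row$mean, 85)
  expect_equal(row$sd, sqrt(50), tolerance = 1e-12)   # 7.0710678
  expect_identical(row$n, 2L)
  expect_false(row$single_record)

  # permutation invariance
  s2 <- summarize_records(rec[2:1, ])
  expect_equal(s2[s2$metric == "test_balanced", ]$mean, 85)

  one <- summarize_records(rec[1, ])
  expect_true(all(one$sd == 0))
  expect_true(all(one$single_record))
})

test_that("a small experiment runs end to end, deterministically", {
  ds <- generate_dataset(synthetic_spec(n_samples = 40, n_features = 120,
                                        n_informative = 30, effect_size = 1.5,
                                        seed = 2))
  cfg <- experiment_config(n_folds = 4, n_repeats = 2, rp_dims = c(NA, 8),
                           classifiers = c("GP", "DT", "KNN"), base_seed = 10,
                           gp = gp_config(population_size = 48,
                                          max_generations = 6))
  ex1 <- run_experiment(ds$matrix, ds$labels, cfg)
  ex2 <- run_experiment(ds$matrix, ds$labels, cfg)
  expect_identical(ex1$records, ex2$records)
  expect_identical(ex1$programs, ex2$programs)

  # one record per classifier x feature set x repeat x fold
  expect_identical(nrow(ex1$records), 3L * 2L * 2L * 4L)
  expect_setequal(unique(ex1$records$rp_dim), c("full", "8"))
  # full pass-through leaves the matrix untouched: GP programs over d features
  expect_true(all(ex1$records$test_balanced >= 0 &
                  ex1$records$test_balanced <= 100))
  # audit trail: summary recomputable from records
  expect_identical(ex1$summary, summarize_records(ex1$records))

  dir <- withr::local_tempdir()
  write_experiment(ex1, dir)
  expect_true(all(file.exists(file.path(dir, c("records.tsv", "summary.tsv",
                                               "best_programs.tsv")))))
  got <- read.delim(file.path(dir, "records.tsv"))
  expect_equal(got$test_balanced, ex1$records$test_balanced)
})

test_that("oversized projection dimensions are rejected up front", {
  ds <- generate_dataset(synthetic_spec(n_samples = 20, n_features = 30,
                                        n_informative = 5, seed = 1))
  cfg <- experiment_config(n_folds = 2, n_repeats = 1, rp_dims = 50,
                           classifiers = "KNN", base_seed = 1)
  expect_error(run_experiment(ds$matrix, ds$labels, cfg), "rp_dims")
})
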