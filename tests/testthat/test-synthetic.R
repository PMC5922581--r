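test_that("generation is deterministic per seed and well-formed", {
  sp <- synthetic_spec(n_samples = 30, n_features = 80, n_informative = 10,
                       seed = 5)
  d1 <- generate_dataset(sp)
  d2 <- generate_dataset(sp)
  expect_identical(d1$matrix, d2$matrix)
  expect_identical(unclass(d1$labels), unclass(d2$labels))
  expect_identical(d1$informative, d2$informative)
  expect_identical(dim(d1$matrix), c(80L, 30L))
  expect_identical(length(d1$informative), 10L)
  expect_false(identical(d1$matrix,
                         generate_dataset(synthetic_spec(30, 80, 10, seed = 6))$matrix))
  # generation does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_dataset(sp)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("the linear shift lands on the informative features only", {
  ds <- generate_dataset(synthetic_spec(n_samples = 400, n_features = 60,
                                        n_informative = 12, effect_size = 1,
                                        baseline_sd = 2, seed = 8))
  y <- unclass(ds$labels)
  shift <- rowMeans(ds$matrix[, y == 1]) - rowMeans(ds$matrix[, y == 0])
  se <- sqrt(1 / sum(y == 1) + 1 / sum(y == 0))
  expect_true(all(abs(shift[ds$informative] - 1) < 4 * se))
  others <- setdiff(seq_len(60), ds$informative)
  expect_lt(max(abs(shift[others])), 5 * se)
})

test_that("the planted linear rule separates classes near the Gaussian bound", {
  # 5 informative features at effect 2: d' = 2 sqrt(5), Bayes error ~1.3%
  ds <- generate_dataset(synthetic_spec(n_samples = 400, n_features = 500,
                                        n_informative = 5, effect_size = 2,
                                        seed = 21))
  y <- unclass(ds$labels)
  score <- colSums(ds$matrix[ds$informative, , drop = FALSE])
  thr <- mean(c(mean(score[y == 1]), mean(score[y == 0])))
  acc <- mean(as.integer(score >= thr) == y)
  expect_gte(acc * 100, 95)
})

test_that("a zero effect size carries no class signal", {
  ds <- generate_dataset(synthetic_spec(n_samples = 200, n_features = 100,
                                        n_informative = 10, effect_size = 0,
                                        seed = 3))
  y <- unclass(ds$labels)
  shift <- rowMeans(ds$matrix[, y == 1]) - rowMeans(ds$matrix[, y == 0])
  expect_lt(max(abs(shift)), 5 * sqrt(1 / 100 + 1 / 100))
})

test_that("the ratio rule labels samples by sign(xa/xb - xc)", {
  ds <- generate_dataset(synthetic_spec(n_samples = 120, n_features = 40,
                                        n_informative = 6,
                                        rule = "nonlinear_ratio", seed = 4))
  abc <- ds$informative
  expect_identical(length(abc), 3L)
  num <- ds$matrix[abc[1], ]; den <- ds$matrix[abc[2], ]
  ratio <- ifelse(abs(den) < 1e-9, 1, num / den)
  expect_identical(as.integer(unclass(ds$labels)),
                   as.integer(ratio - ds$matrix[abc[3], ] >= 0))
  expect_true(all(table(unclass(ds$labels)) >= 2))

  # the division primitive suffices to express the rule exactly
  oracle <- parse_tree("(sub (div x1 x2) x3)", 3)
  pred <- classify(oracle, ds$matrix[abc, ])
  expect_identical(pred, as.integer(unclass(ds$labels)))
})

test_that("GP recovers the ratio rule given the true features", {
  ds <- generate_dataset(synthetic_spec(n_samples = 100, n_features = 30,
                                        n_informative = 5,
                                        rule = "nonlinear_ratio", seed = 12))
  X <- ds$matrix[ds$informative, ]
  fit <- evolve(X, unclass(ds$labels),
                gp_config(population_size = 128, max_generations = 20, seed = 2))
  expect_gte(fit$best_fitness, 0.9)
})

test_that("degenerate specifications are refused", {
  expect_error(synthetic_spec(n_informative = 200, n_features = 100), "informative")
  expect_error(synthetic_spec(class_balance = 1), "class_balance")
  expect_error(synthetic_spec(class_balance = 0.01, n_samples = 50), "fewer than 2")
  expect_error(synthetic_spec(noise_sd = 0), "noise_sd")
  expect_error(synthetic_spec(rule = "nonlinear_ratio", n_informative = 2),
               "at least 3")
})

test_that("datasets are written in the package's text formats", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(synthetic_spec(n_samples = 12, n_features = 20,
                                        n_informative = 4, seed = 9))
  write_dataset(ds, dir)
  m <- read_expression(file.path(dir, "matrix.tsv"))
  expect_identical(m, ds$matrix)
  y <- read_labels(file.path(dir, "labels.tsv"), "case")
  expect_identical(unclass(y), unclass(ds$labels))
  truth <- readLines(file.path(dir, "truth.tsv"))[-1]
  expect_identical(truth, rownames(ds$matrix)[ds$informative])
})

test_that("test accuracy is non-decreasing in the planted effect size", {
  effects <- c(0, 0.5, 1, 2)
  means <- numeric(length(effects))
  ses <- numeric(length(effects))
  for (i in seq_along(effects)) {
    ds <- generate_dataset(synthetic_spec(n_samples = 80, n_features = 400,
                                          n_informative = 40,
                                          effect_size = effects[i], seed = 100))
    cfg <- experiment_config(n_folds = 4, n_repeats = 1, rp_dims = 20,
                             classifiers = "GP", base_seed = 7,
                             gp = gp_config(population_size = 128,
                                            max_generations = 15))
    ex <- run_experiment(ds$matrix, ds$labels, cfg)
    means[i] <- mean(ex$records$test_balanced)
    ses[i] <- sd(ex$records$test_balanced) / sqrt(nrow(ex$records))
  }
  pooled <- sqrt(mean(ses^2))
  expect_true(all(diff(means) >= -pooled))
})
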