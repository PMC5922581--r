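#' Specify a synthetic microarray-like dataset
#'
#' Describes a dataset with the shape of a typical two-class expression
#' study: around a hundred samples, thousands to tens of thousands of
#' features, a planted informative subset and heavy independent noise.
#' Each feature carries its own baseline level (drawn once per feature
#' from `N(0, baseline_sd^2)`), emulating the heterogeneous probe
#' intensities of real arrays; on top of that, samples get independent
#' Gaussian noise with standard deviation `noise_sd`, optionally in
#' equicorrelated blocks.
#'
#' Two planted rules are available.  `"linear_shift"` adds
#' `effect_size * noise_sd` to every informative feature of the positive
#' class, so `effect_size` is the standardized mean shift per informative
#' feature.  `"nonlinear_ratio"` instead labels each sample by the sign
#' rule `x_a / x_b - x_c >= 0` over three informative features (with the
#' same protected division as the GP primitives), producing a class signal
#' that genuinely requires the division primitive; under this rule
#' `effect_size` and `class_balance` are ignored, since labels derive from
#' the data.
#'
#' @param n_samples number of samples (default 100).
#' @param n_features number of features (default 10000).
#' @param n_informative size of the planted informative subset (default
#'   500, i.e. 5 percent of the default feature count).
#' @param effect_size standardized mean shift per informative feature
#'   (default 0.75).
#' @param class_balance proportion of positive samples in (0, 1).
#' @param noise_sd per-sample noise standard deviation (default 1).
#' @param baseline_sd spread of per-feature baseline levels (default 2).
#' @param correlation_block_size 0 for independent features, otherwise
#'   features are grouped into blocks of this size with pairwise
#'   correlation 0.5.
#' @param rule `"linear_shift"` or `"nonlinear_ratio"`.
#' @param seed integer seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 100L, n_features = 10000L,
                           n_informative = 500L, effect_size = 0.75,
                           class_balance = 0.5, noise_sd = 1,
                           baseline_sd = 2, correlation_block_size = 0L,
                           rule = c("linear_shift", "nonlinear_ratio"),
                           seed = 1L) {
  rule <- match.arg(rule)
  spec <- list(n_samples = as.integer(n_samples),
               n_features = as.integer(n_features),
               n_informative = as.integer(n_informative),
               effect_size = effect_size, class_balance = class_balance,
               noise_sd = noise_sd, baseline_sd = baseline_sd,
               correlation_block_size = as.integer(correlation_block_size),
               rule = rule, seed = as.integer(seed))
  with(spec, {
    if (n_samples < 4L) stopf("need at least 4 samples")
    if (n_features < 1L) stopf("need at least 1 feature")
    if (n_informative < 0L || n_informative > n_features)
      stopf("n_informative must lie in [0, n_features]")
    if (rule == "nonlinear_ratio" && n_informative < 3L)
      stopf("nonlinear_ratio needs at least 3 informative features")
    if (class_balance <= 0 || class_balance >= 1)
      stopf("class_balance must lie strictly in (0, 1)")
    if (round(class_balance * n_samples) < 2L ||
        round((1 - class_balance) * n_samples) < 2L)
      stopf("class_balance leaves a class with fewer than 2 samples")
    if (noise_sd <= 0 || effect_size < 0 || baseline_sd < 0)
      stopf("noise_sd must be positive; effect_size and baseline_sd non-negative")
    if (correlation_block_size < 0L) stopf("correlation_block_size must be >= 0")
  })
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0("synthetic_spec: %d samples x %d features, %d informative, ",
                     "effect %.2f, rule %s, seed %d\n"),
              x$n_samples, x$n_features, x$n_informative, x$effect_size,
              x$rule, x$seed))
  invisible(x)
}

#' Generate a synthetic expression dataset
#'
#' Draws the dataset described by a [synthetic_spec()]: deterministic per
#' seed, returning the expression matrix, the labels and the planted
#' ground truth.
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `synthetic_dataset`: list with `matrix`
#'   (features x samples, see [expression_matrix()]), `labels` (a
#'   [label_vector()] with positive class `"case"`), `informative`
#'   (indices of the planted features) and `spec`.
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_samples = 20, n_features = 50,
#'                                       n_informative = 5, seed = 42))
#' dim(ds$matrix)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples; d <- spec$n_features
    baseline <- rnorm(d, 0, spec$baseline_sd)
    X <- matrix(rnorm(d * n, 0, spec$noise_sd), d, n)
    b <- spec$correlation_block_size
    if (b > 1L) {
      # equicorrelated blocks, rho = 0.5: x = (e + shared) / sqrt(2)
      blocks <- rep(seq_len(ceiling(d / b)), each = b, length.out = d)
      shared <- matrix(rnorm(max(blocks) * n, 0, spec$noise_sd), max(blocks), n)
      X <- (X + shared[blocks, , drop = FALSE]) / sqrt(2)
    }
    X <- X + baseline
    informative <- sort(sample.int(d, spec$n_informative))

    if (spec$rule == "linear_shift") {
      n_pos <- round(spec$class_balance * n)
      y <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
      if (spec$n_informative > 0L && spec$effect_size > 0)
        X[informative, y == 1L] <- X[informative, y == 1L] +
          spec$effect_size * spec$noise_sd
    } else {
      abc <- informative[1:3]
      den <- X[abc[2L], ]
      ratio <- ifelse(abs(den) < 1e-9, 1, X[abc[1L], ] / den)
      y <- as.integer(ratio - X[abc[3L], ] >= 0)
      if (length(unique(y)) < 2L || min(table(y)) < 2L)
        stopf("degenerate draw: ratio rule produced a near-single-class labelling; use another seed")
      informative <- abc
    }

    m <- expression_matrix(X,
                           feature_ids = sprintf("f%05d", seq_len(d)),
                           sample_ids  = sprintf("s%03d", seq_len(n)))
    labels <- label_vector(ifelse(y == 1L, "case", "control"), "case",
                           sample_ids = colnames(m))
    structure(list(matrix = m, labels = labels, informative = informative,
                   spec = spec),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d features x %d samples (%d cases), rule %s\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$labels == 1L), x$spec$rule))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Writes `matrix.tsv`, `labels.tsv` and `truth.tsv` (the planted
#' informative feature identifiers) in the package's delimited formats.
#'
#' @param ds a [generate_dataset()] result.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(ds$matrix, file.path(dir, "matrix.tsv"))
  write_labels(ds$labels, file.path(dir, "labels.tsv"))
  writeLines(c("feature_id", rownames(ds$matrix)[ds$informative]),
             file.path(dir, "truth.tsv"))
  invisible(dir)
}
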