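#' Stratified cross-validation folds
#'
#' Partitions samples into `n_folds` disjoint test folds preserving class
#' proportions: within each class, shuffled members are dealt round-robin,
#' so per-fold class counts differ from exact proportionality by at most
#' one.  Every class must have at least `n_folds` members, which guarantees
#' both classes appear in every test fold (required by [test_accuracy()]).
#'
#' @param y 0/1 labels ([label_vector()] or plain vector).
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed; the assignment is deterministic given
#'   `(y, n_folds, seed)` and the caller's RNG state is untouched.
#' @return a list of `n_folds` lists with integer index vectors `train`
#'   and `test`.
#' @export
stratified_folds <- function(y, n_folds, seed) {
  y <- as.integer(unclass(y))
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stopf("need at least 2 folds")
  counts <- table(factor(y, levels = 0:1))
  if (any(counts < n_folds))
    stopf("smallest class has %d members; cannot stratify into %d folds",
          min(counts), n_folds)
  assign <- integer(length(y))
  with_seed(seed, {
    for (cls in 0:1) {
      idx <- sample(which(y == cls))
      assign[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  lapply(seq_len(n_folds), function(f)
    list(train = which(assign != f), test = which(assign == f)))
}

#' Fit a baseline classifier
#'
#' Trains one of the comparison classifiers on an expression matrix.
#' Implementations are the standard R packages: `rpart` (DT),
#' `e1071::naiveBayes` (NB), `class::knn` (KNN, deferred to prediction
#' time), `e1071::svm` (SVM) and `randomForest` (RF).  All use their
#' library defaults except KNN's neighbour count and the decision tree,
#' which is grown fully (`minsplit = 2`, `cp = 0`, no internal
#' cross-validation) in the style of Weka-like C4.5 trees so it can
#' memorize separable training data.
#'
#' @param name one of `"DT"`, `"NB"`, `"KNN"`, `"SVM"`, `"RF"`.
#' @param train_X training features x samples matrix.
#' @param train_y aligned 0/1 labels.
#' @param seed seed for the stochastic fitters (RF, and rpart's internal
#'   cross-validation); RNG state is restored afterwards.
#' @param knn_k neighbours for KNN (default 3).
#' @return an object of class `rpgp_baseline` with a `predict()` method
#'   returning 0/1 per sample.
#' @export
fit_baseline <- function(name, train_X, train_y, seed = NULL, knn_k = 3L) {
  name <- match.arg(name, c("DT", "NB", "KNN", "SVM", "RF"))
  y <- factor(as.integer(unclass(train_y)), levels = 0:1)
  df <- as.data.frame(t(train_X))
  colnames(df) <- make.names(colnames(df), unique = TRUE)
  fit <- with_seed(seed, switch(
    name,
    DT  = rpart::rpart(.rpgp_class ~ ., data = cbind(df, .rpgp_class = y),
                       method = "class",
                       control = rpart::rpart.control(minsplit = 2L,
                                                      minbucket = 1L,
                                                      cp = 0, xval = 0L)),
    NB  = e1071::naiveBayes(x = df, y = y),
    KNN = list(train = df, cl = y, k = as.integer(knn_k)),
    SVM = e1071::svm(x = df, y = y),
    RF  = randomForest::randomForest(x = df, y = y)))
  structure(list(name = name, fit = fit, features = colnames(df),
                 raw_features = rownames(train_X)),
            class = "rpgp_baseline")
}

#' @export
print.rpgp_baseline <- function(x, ...) {
  cat(sprintf("rpgp_baseline: %s over %d features\n", x$name, length(x$features)))
  invisible(x)
}

#' Predict with a baseline classifier
#'
#' @param object an [fit_baseline()] result.
#' @param newdata features x samples matrix in the training feature space.
#' @param ... unused.
#' @return integer 0/1 vector, one prediction per sample.
#' @export
predict.rpgp_baseline <- function(object, newdata, ...) {
  if (nrow(newdata) != length(object$raw_features))
    stopf("feature mismatch: model saw %d features, newdata has %d",
          length(object$raw_features), nrow(newdata))
  df <- as.data.frame(t(newdata))
  colnames(df) <- object$features
  out <- switch(object$name,
    DT  = predict(object$fit, df, type = "class"),
    NB  = predict(object$fit, df),
    KNN = class::knn(object$fit$train, df, object$fit$cl, k = object$fit$k),
    SVM = predict(object$fit, df),
    RF  = predict(object$fit, df))
  as.integer(as.character(out))
}

#' Experiment configuration
#'
#' Describes one benchmark: stratified `n_folds`-fold cross-validation,
#' repeated `n_repeats` times under the seed schedule
#' `base_seed + repeat`, for every requested feature set (each entry of
#' `rp_dims` is a random-projection target dimension, `NA` meaning the
#' full untransformed feature set) and every requested classifier.
#'
#' One projection matrix is built per repetition (from that repetition's
#' seed) and shared by all its folds; since the projection never sees the
#' data, this cannot leak test information.  Set
#' `regenerate_per_fold = TRUE` to draw a fresh projection per fold
#' instead.
#'
#' @param n_folds folds per repetition (default 10).
#' @param n_repeats repetitions (default 30).
#' @param rp_dims numeric vector of projection dimensions, `NA` for the
#'   full feature set; default `c(50, 100, 150)`.
#' @param classifiers subset of `c("GP","DT","NB","KNN","SVM","RF")`.
#' @param knn_k neighbours for KNN (default 3).
#' @param base_seed integer; repetition `r` uses `base_seed + r`.
#' @param gp a [gp_config()] for the GP classifier.
#' @param regenerate_per_fold draw one projection per fold rather than per
#'   repetition.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(n_folds = 10L, n_repeats = 30L,
                              rp_dims = c(50, 100, 150),
                              classifiers = c("GP", "DT", "NB", "KNN", "SVM", "RF"),
                              knn_k = 3L, base_seed = 1L,
                              gp = gp_config(),
                              regenerate_per_fold = FALSE) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  if (length(rp_dims) == 0L) rp_dims <- NA_real_
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 rp_dims = rp_dims, classifiers = classifiers,
                 knn_k = as.integer(knn_k), base_seed = as.integer(base_seed),
                 gp = gp, regenerate_per_fold = isTRUE(regenerate_per_fold)),
            class = "experiment_config")
}

record_row <- function(classifier, rp_dim, rep, fold, pred_tr, y_tr, pred_te, y_te) {
  ctr <- confusion(pred_tr, y_tr)
  cte <- confusion(pred_te, y_te)
  data.frame(classifier = classifier,
             rp_dim = if (is.na(rp_dim)) "full" else as.character(rp_dim),
             rep = rep, fold = fold,
             train_mcc100 = training_accuracy(ctr),
             train_pct = percent_correct(ctr),
             test_balanced = test_accuracy(cte))
}

#' Run a cross-validated benchmark experiment
#'
#' For every repetition: derive the repetition seed, build the projection
#' matrices (one per requested dimension), project all samples, draw
#' stratified folds, and for every fold and classifier train on the
#' training split and record training accuracy (MCC x 100 and percent
#' correct) plus balanced test accuracy.  The GP classifier is trained
#' with [evolve()] (fold-level seed `repeat_seed * 1000 + fold`), the
#' others with [fit_baseline()].  The whole run is deterministic given
#' `(m, y, cfg)`.
#'
#' @param m expression matrix, features x samples.
#' @param y aligned [label_vector()].
#' @param cfg an [experiment_config()].
#' @return an object of class `rpgp_experiment`: list with `records` (one
#'   row per classifier x rp_dim x repetition x fold), `summary` (from
#'   [summarize_records()]), `programs` (best GP S-expressions), and
#'   `config`.
#' @export
run_experiment <- function(m, y, cfg = experiment_config()) {
  stopifnot(inherits(cfg, "experiment_config"))
  validate_expression(m)
  assert_aligned(m, y)
  yv <- as.integer(unclass(y))
  d <- nrow(m)
  bad <- cfg$rp_dims[!is.na(cfg$rp_dims) & cfg$rp_dims >= d]
  if (length(bad))
    stopf("rp_dims must be < number of features (%d); offending: %s",
          d, paste(bad, collapse = ", "))

  records <- vector("list", 0L)
  programs <- list()
  for (r in seq_len(cfg$n_repeats)) {
    seed_r <- cfg$base_seed + r
    folds <- stratified_folds(yv, cfg$n_folds, seed = seed_r)
    for (ki in seq_along(cfg$rp_dims)) {
      kdim <- cfg$rp_dims[ki]
      if (!cfg$regenerate_per_fold) {
        Xall <- if (is.na(kdim)) m else
          project(m, build_projection(d, kdim, seed = seed_r))
      }
      for (f in seq_along(folds)) {
        if (cfg$regenerate_per_fold) {
          Xall <- if (is.na(kdim)) m else
            project(m, build_projection(d, kdim, seed = seed_r * 100L + f))
        }
        tr <- folds[[f]]$train; te <- folds[[f]]$test
        Xtr <- Xall[, tr, drop = FALSE]; Xte <- Xall[, te, drop = FALSE]
        ytr <- yv[tr]; yte <- yv[te]
        for (cl in cfg$classifiers) {
          if (cl == "GP") {
            gcfg <- cfg$gp
            gcfg$seed <- seed_r * 1000L + f
            model <- evolve(Xtr, ytr, gcfg)
            ptr <- predict(model, Xtr); pte <- predict(model, Xte)
            programs[[sprintf("rep%d_%s_fold%d", r,
                              if (is.na(kdim)) "full" else paste0("rp", kdim),
                              f)]] <- format(model$best_tree)
          } else {
            model <- fit_baseline(cl, Xtr, ytr, seed = seed_r * 1000L + f,
                                  knn_k = cfg$knn_k)
            ptr <- predict(model, Xtr); pte <- predict(model, Xte)
          }
          records[[length(records) + 1L]] <-
            record_row(cl, kdim, r, f, ptr, ytr, pte, yte)
        }
      }
    }
  }
  records <- do.call(rbind, records)
  structure(list(records = records, summary = summarize_records(records),
                 programs = programs, config = cfg),
            class = "rpgp_experiment")
}

#' Summarize per-fold records into mean +/- sd
#'
#' Aggregates the per-(repetition, fold) accuracies of [run_experiment()]
#' into mean and sample standard deviation per classifier and feature set,
#' for each metric.  A cell with a single record reports `sd = 0` and is
#' flagged in the `single_record` column; the aggregates are recomputable
#' from the records at any time.
#'
#' @param records the `records` data.frame of an experiment.
#' @return data.frame with columns `classifier`, `rp_dim`, `metric`,
#'   `mean`, `sd`, `n`, `single_record`.
#' @export
summarize_records <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  metrics <- c("train_mcc100", "train_pct", "test_balanced")
  out <- list()
  for (met in metrics) {
    agg <- stats::aggregate(records[[met]],
                            by = list(classifier = records$classifier,
                                      rp_dim = records$rp_dim),
                            FUN = function(v) c(mean = mean(v),
                                                sd = if (length(v) > 1L) sd(v) else 0,
                                                n = length(v)))
    out[[met]] <- data.frame(classifier = agg$classifier, rp_dim = agg$rp_dim,
                             metric = met,
                             mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                             n = as.integer(agg$x[, "n"]),
                             single_record = agg$x[, "n"] == 1)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$metric, res$classifier, res$rp_dim), ]
}

#' @export
print.rpgp_experiment <- function(x, ...) {
  s <- x$summary[x$summary$metric == "test_balanced", ]
  cat(sprintf("rpgp_experiment: %d records (%d repeats x %d folds)\n",
              nrow(x$records), x$config$n_repeats, x$config$n_folds))
  cat("balanced test accuracy (mean +/- sd):\n")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-4s %-5s %6.2f +/- %.2f  (n = %d)\n", s$classifier[i],
                s$rp_dim[i], s$mean[i], s$sd[i], s$n[i]))
  invisible(x)
}

#' Write experiment outputs to a directory
#'
#' Writes `records.tsv` (one row per fold), `summary.tsv` (mean +/- sd)
#' and, when GP was run, `best_programs.tsv` with the winning
#' S-expressions.
#'
#' @param x an `rpgp_experiment`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(x, dir) {
  stopifnot(inherits(x, "rpgp_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x$records, file.path(dir, "records.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$summary, file.path(dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(x$programs))
    utils::write.table(data.frame(run = names(x$programs),
                                  program = unlist(x$programs)),
                       file.path(dir, "best_programs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}
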