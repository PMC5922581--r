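#' Genetic-programming configuration
#'
#' Collects the evolutionary parameters.  Defaults follow the standard
#' settings for this classifier: population 1024, tournament size 7,
#' crossover probability 0.8, mutation probability 0.2, ramped
#' half-and-half initialization over depths 2–8, a hard depth cap of 8,
#' single-individual elitism, and termination after a fixed number of
#' generations (50 by default; the stopping rule is reaching the maximum
#' generation count).
#'
#' Offspring are produced by an exclusive choice per offspring: crossover
#' with probability `crossover_prob`, subtree mutation with
#' `mutation_prob`, and plain reproduction with the remainder (the two
#' defaults sum to 1, so reproduction is off by default).
#'
#' @param population_size number of individuals per generation.
#' @param tournament_size individuals sampled (with replacement) per
#'   tournament.
#' @param crossover_prob,mutation_prob operator-selection probabilities;
#'   their sum must not exceed 1.
#' @param init_depth_min,init_depth_max ramp range for initialization.
#' @param max_depth hard cap on tree depth throughout evolution.
#' @param elites number of best individuals copied unchanged each
#'   generation.
#' @param max_generations generations to run before termination.
#' @param seed integer seed for the whole run, or `NULL` to use the current
#'   RNG stream.
#' @return an object of class `gp_config`.
#' @seealso [gp_config_reduced()] for a desk-scale budget.
#' @export
gp_config <- function(population_size = 1024L, tournament_size = 7L,
                      crossover_prob = 0.8, mutation_prob = 0.2,
                      init_depth_min = 2L, init_depth_max = 8L,
                      max_depth = 8L, elites = 1L,
                      max_generations = 50L, seed = NULL) {
  cfg <- list(population_size = as.integer(population_size),
              tournament_size = as.integer(tournament_size),
              crossover_prob = crossover_prob,
              mutation_prob = mutation_prob,
              init_depth_min = as.integer(init_depth_min),
              init_depth_max = as.integer(init_depth_max),
              max_depth = as.integer(max_depth),
              elites = as.integer(elites),
              max_generations = as.integer(max_generations),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  with(cfg, {
    if (population_size < 1L || tournament_size < 1L || elites < 0L ||
        max_generations < 1L)
      stopf("counts in gp_config must be positive")
    if (tournament_size > population_size)
      stopf("tournament_size cannot exceed population_size")
    if (elites >= population_size) stopf("elites must be < population_size")
    if (crossover_prob < 0 || mutation_prob < 0 ||
        crossover_prob + mutation_prob > 1 + 1e-12)
      stopf("crossover_prob + mutation_prob must be <= 1")
    if (!(init_depth_min <= init_depth_max && init_depth_max <= max_depth))
      stopf("need init_depth_min <= init_depth_max <= max_depth")
  })
  structure(cfg, class = "gp_config")
}

#' Reduced-budget GP configuration
#'
#' The bundled desk-scale profile: population 256 and 30 generations, all
#' other settings as [gp_config()].  Intended for tests, examples and
#' synthetic benchmarks where the full budget is unnecessary.
#'
#' @param ... overrides passed on to [gp_config()].
#' @return a `gp_config`.
#' @export
gp_config_reduced <- function(...) {
  args <- list(...)
  if (is.null(args$population_size)) args$population_size <- 256L
  if (is.null(args$max_generations)) args$max_generations <- 30L
  do.call(gp_config, args)
}

#' @export
print.gp_config <- function(x, ...) {
  cat(sprintf(paste0("gp_config: pop %d, tournament %d, pX %.2f, pM %.2f, ",
                     "init depth %d-%d, cap %d, elites %d, %d generations\n"),
              x$population_size, x$tournament_size, x$crossover_prob,
              x$mutation_prob, x$init_depth_min, x$init_depth_max,
              x$max_depth, x$elites, x$max_generations))
  invisible(x)
}

# Planned ramp-level sizes for ramped half-and-half: as even a split of the
# population over the depth levels as integer counts allow.
ramp_level_sizes <- function(population_size, init_depth_min, init_depth_max) {
  levels <- seq.int(init_depth_min, init_depth_max)
  n <- length(levels)
  sizes <- rep(population_size %/% n, n)
  extra <- population_size %% n
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stats::setNames(sizes, levels)
}

init_pop_ <- function(cfg, k) {
  sizes <- ramp_level_sizes(cfg$population_size, cfg$init_depth_min,
                            cfg$init_depth_max)
  trees <- vector("list", cfg$population_size)
  pos <- 1L
  for (lev in seq_along(sizes)) {
    depth <- as.integer(names(sizes)[lev])
    n_full <- sizes[lev] %/% 2L          # odd counts: extra tree to "grow"
    n_grow <- sizes[lev] - n_full
    for (i in seq_len(n_full)) {
      trees[[pos]] <- grow_random_tree(k, depth, method = "full"); pos <- pos + 1L
    }
    for (i in seq_len(n_grow)) {
      trees[[pos]] <- grow_random_tree(k, depth, min_depth = cfg$init_depth_min,
                                       method = "grow"); pos <- pos + 1L
    }
  }
  structure(list(trees = trees, fitness = rep(NA_real_, length(trees)),
                 generation = 0L, best_tree = NULL, best_fitness = -Inf),
            class = "gp_population")
}

#' Initialize a GP population (ramped half-and-half)
#'
#' Depth targets are ramped uniformly over
#' `[init_depth_min, init_depth_max]`; at each depth level half the trees
#' are built with the "full" method and half with the "grow" method (grow
#' leaves are never shallower than `init_depth_min`, so every initial tree
#' has depth within the ramp range).
#'
#' @param cfg a [gp_config()]; `cfg$seed`, if set, seeds the draw.
#' @param k number of terminal features.
#' @return an object of class `gp_population`.
#' @export
init_population <- function(cfg, k) {
  stopifnot(inherits(cfg, "gp_config"), k >= 1L)
  maybe_seed(cfg$seed)
  init_pop_(cfg, as.integer(k))
}

#' @export
print.gp_population <- function(x, ...) {
  cat(sprintf("gp_population: %d individuals, generation %d, best fitness %s\n",
              length(x$trees), x$generation,
              if (is.finite(x$best_fitness)) sprintf("%.4f", x$best_fitness) else "unevaluated"))
  invisible(x)
}

# Tournament on a fitness vector; returns the winning index.  Ties among
# the sampled maximum are broken uniformly at random.
tournament_idx <- function(fitness, size) {
  cand <- sample.int(length(fitness), size, replace = TRUE)
  f <- fitness[cand]
  winners <- cand[f == max(f)]
  if (length(winners) == 1L) winners else winners[sample.int(length(winners), 1L)]
}

#' Tournament selection
#'
#' Samples `size` individuals uniformly with replacement and returns the
#' one with maximal fitness, breaking ties uniformly at random.  The
#' population must already carry fitness values (as inside [evolve()]).
#'
#' @param pop a `gp_population` with non-missing `fitness`.
#' @param size tournament size.
#' @return the selected `gp_tree`.
#' @export
tournament_select <- function(pop, size) {
  stopifnot(inherits(pop, "gp_population"))
  if (length(pop$trees) == 0L) stopf("empty population")
  if (anyNA(pop$fitness)) stopf("population fitness not evaluated")
  if (size > length(pop$trees)) stopf("tournament size exceeds population size")
  pop$trees[[tournament_idx(pop$fitness, size)]]
}

# splice subtree `sub` (prefix code) over the subtree rooted at node i of `code`
splice_code <- function(code, i, sub) {
  j <- subtree_end_cpp(code, i)
  c(if (i > 1L) code[seq_len(i - 1L)], sub,
    if (j < length(code)) code[seq.int(j + 1L, length(code))])
}

#' Subtree crossover
#'
#' Returns a copy of `a` in which a uniformly chosen node is replaced by a
#' uniformly chosen subtree of `b`.  If the child would exceed `max_depth`,
#' the draw is retried up to `retries` times; on exhaustion a copy of `a`
#' is returned, so the depth cap is never violated.
#'
#' @param a,b parent `gp_tree`s over the same feature space.
#' @param max_depth hard depth cap for the child.
#' @param retries bounded number of re-draws on depth violation.
#' @return a `gp_tree`.
#' @export
subtree_crossover <- function(a, b, max_depth = 8L, retries = 10L) {
  stopifnot(inherits(a, "gp_tree"), inherits(b, "gp_tree"))
  for (r in seq_len(retries)) {
    i <- sample.int(length(a$code), 1L)
    j <- sample.int(length(b$code), 1L)
    sub <- b$code[seq.int(j, subtree_end_cpp(b$code, j))]
    child <- splice_code(a$code, i, sub)
    if (max(node_depths_cpp(child)) <= max_depth)
      return(new_tree(child, a$n_features))
  }
  a
}

#' Subtree mutation
#'
#' Replaces a uniformly chosen node of `a` by a freshly grown random
#' subtree whose depth respects the configuration's `max_depth` at the
#' node's position.
#'
#' @param a a `gp_tree`.
#' @param cfg a [gp_config()] supplying `max_depth`.
#' @return a `gp_tree`.
#' @export
subtree_mutate <- function(a, cfg) {
  stopifnot(inherits(a, "gp_tree"), inherits(cfg, "gp_config"))
  i <- sample.int(length(a$code), 1L)
  room <- cfg$max_depth - node_depths_cpp(a$code)[i]
  sub <- grow_code(a$n_features, max(room, 0L), 0L, "grow")
  new_tree(splice_code(a$code, i, sub), a$n_features)
}

# standardized-MCC fitness of one prefix code on Xt (samples x features,
# the transpose kept by evolve() for contiguous feature access), y 0/1
fitness_of <- function(code, Xt, y) {
  pred <- as.integer(eval_prefix_t_cpp(code, Xt) >= 0)
  standardized_fitness(mcc(confusion(pred, y)))
}

#' Evolve a GP classifier
#'
#' Runs the full evolutionary loop: ramped half-and-half initialization,
#' fitness = standardized MCC `(1 + MCC)/2` of the zero-threshold
#' classifier on the training samples, tournament selection, subtree
#' crossover/mutation/reproduction chosen exclusively per offspring, and
#' elitism (the `elites` best individuals are copied unchanged, so the
#' best-ever fitness is non-decreasing).  Termination is after
#' `max_generations` generations.
#'
#' @param train_X training expression matrix, features x samples (typically
#'   the output of [project()]).
#' @param train_y aligned 0/1 labels ([label_vector()] or plain vector);
#'   both classes must have at least 2 samples.
#' @param cfg a [gp_config()]; `cfg$seed` makes the run fully reproducible.
#' @return an object of class `gp_model`: list with `best_tree`,
#'   `best_fitness`, `trace` (data.frame of generation and best-ever
#'   fitness, generation 0 = initial population), `config`, and
#'   `feature_ids`.
#' @examples
#' X <- matrix(rnorm(2 * 40), 2, 40,
#'             dimnames = list(c("a", "b"), paste0("s", 1:40)))
#' y <- as.integer(X[1, ] - X[2, ] >= 0)
#' fit <- evolve(X, y, gp_config(population_size = 64, max_generations = 10,
#'                               seed = 1))
#' fit$best_fitness
#' @export
evolve <- function(train_X, train_y, cfg = gp_config()) {
  stopifnot(inherits(cfg, "gp_config"))
  if (!is.matrix(train_X) || !is.numeric(train_X))
    stopf("train_X must be a numeric matrix (features x samples)")
  y <- as.integer(unclass(train_y))
  if (length(y) != ncol(train_X))
    stopf("alignment error: %d labels but %d samples", length(y), ncol(train_X))
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    stopf("training data must contain >= 2 samples of each class (MCC is degenerate otherwise)")
  k <- nrow(train_X)
  Xt <- t(train_X)
  maybe_seed(cfg$seed)

  pop <- init_pop_(cfg, k)
  pop$fitness <- vapply(pop$trees, function(t) fitness_of(t$code, Xt, y),
                        numeric(1L))
  update_best <- function(pop) {
    top <- which(pop$fitness == max(pop$fitness))
    if (length(top) > 1L) top <- top[sample.int(length(top), 1L)]
    if (pop$fitness[top] > pop$best_fitness) {
      pop$best_fitness <- pop$fitness[top]
      pop$best_tree <- pop$trees[[top]]
    }
    pop
  }
  pop <- update_best(pop)
  trace <- numeric(cfg$max_generations + 1L)
  trace[1L] <- pop$best_fitness

  n <- cfg$population_size
  for (gen in seq_len(cfg$max_generations)) {
    trees <- vector("list", n)
    fit <- rep(NA_real_, n)
    n_el <- cfg$elites
    if (n_el > 0L) {                      # elite slots, ties broken randomly
      ord <- order(pop$fitness, runif(n), decreasing = TRUE)[seq_len(n_el)]
      trees[seq_len(n_el)] <- pop$trees[ord]
      fit[seq_len(n_el)] <- pop$fitness[ord]
    }
    for (s in seq.int(n_el + 1L, n)) {
      u <- runif(1L)
      if (u < cfg$crossover_prob) {
        p1 <- pop$trees[[tournament_idx(pop$fitness, cfg$tournament_size)]]
        p2 <- pop$trees[[tournament_idx(pop$fitness, cfg$tournament_size)]]
        trees[[s]] <- subtree_crossover(p1, p2, cfg$max_depth)
      } else if (u < cfg$crossover_prob + cfg$mutation_prob) {
        p1 <- pop$trees[[tournament_idx(pop$fitness, cfg$tournament_size)]]
        trees[[s]] <- subtree_mutate(p1, cfg)
      } else {
        idx <- tournament_idx(pop$fitness, cfg$tournament_size)
        trees[[s]] <- pop$trees[[idx]]
        fit[s] <- pop$fitness[idx]
      }
    }
    miss <- which(is.na(fit))
    fit[miss] <- vapply(trees[miss], function(t) fitness_of(t$code, Xt, y),
                        numeric(1L))
    pop$trees <- trees
    pop$fitness <- fit
    pop$generation <- gen
    pop <- update_best(pop)
    trace[gen + 1L] <- pop$best_fitness
  }

  structure(list(best_tree = pop$best_tree,
                 best_fitness = pop$best_fitness,
                 trace = data.frame(generation = 0:cfg$max_generations,
                                    best_fitness = trace),
                 config = cfg,
                 feature_ids = rownames(train_X)),
            class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf("gp_model: training fitness %.4f after %d generations\n  %s\n",
              x$best_fitness, max(x$trace$generation), format(x$best_tree)))
  invisible(x)
}

#' Predict with an evolved GP classifier
#'
#' @param object a `gp_model` from [evolve()].
#' @param newdata feature matrix (features x samples) in the same feature
#'   space the model was trained on.
#' @param type `"class"` for 0/1 labels, `"score"` for the raw signed
#'   program output.
#' @param ... unused.
#' @return integer or numeric vector, one value per sample.
#' @export
predict.gp_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (type == "class") classify(object$best_tree, newdata)
  else eval_tree(object$best_tree, newdata)
}

#' Write a best-fitness trace as TSV
#'
#' Two columns: `generation` and `best_fitness`.
#'
#' @param model a `gp_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(model, path) {
  utils::write.table(model$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
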