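# Prefix-encoded program trees.
#
# A program is an integer vector in prefix (Polish) order: positive entries
# are terminals (1-based feature indices), negative entries are the binary
# operators -1 add, -2 sub, -3 mul, -4 protected div.  A subtree is always a
# contiguous slice, so the genetic operators are vector splices.

OP_CODES <- c(add = -1L, sub = -2L, mul = -3L, div = -4L)
OP_NAMES <- c("add", "sub", "mul", "div")

# internal constructor for codes that are valid by construction
# (genetic operators): skips the O(n) structural scan of gp_tree()
new_tree <- function(code, n_features) {
  structure(list(code = code, n_features = n_features), class = "gp_tree")
}

#' Construct a program tree
#'
#' Builds (and validates) a GP individual from its prefix code.  Most users
#' obtain trees from [grow_random_tree()], [init_population()] or [evolve()]
#' rather than by hand.
#'
#' @param code integer vector in prefix order; positive = terminal feature
#'   index, negative in `-1..-4` = operator (add, sub, mul, div).
#' @param n_features number of features the terminals may index.
#' @return an object of class `gp_tree`.
#' @examples
#' t <- gp_tree(c(-2L, 1L, 2L), n_features = 2)  # (sub x1 x2)
#' format(t)
#' @export
gp_tree <- function(code, n_features) {
  code <- as.integer(code)
  n_features <- as.integer(n_features)
  if (length(code) < 1L || anyNA(code) || any(code == 0L) || any(code < -4L))
    stopf("invalid program code")
  if (max(code) > n_features)
    stopf("terminal index %d out of range for %d features", max(code), n_features)
  need <- 1L
  for (i in seq_along(code)) {
    need <- need + if (code[i] < 0L) 1L else -1L
    if (need == 0L && i < length(code)) stopf("trailing nodes after complete program")
  }
  if (need != 0L) stopf("incomplete program code")
  structure(list(code = code, n_features = n_features), class = "gp_tree")
}

#' Number of nodes in a program tree
#' @param t a `gp_tree`.
#' @return integer node count.
#' @export
tree_size <- function(t) length(t$code)

#' Depth of a program tree
#'
#' A single terminal has depth 0; depth is the number of edges on the
#' longest root-to-leaf path.
#'
#' @param t a `gp_tree`.
#' @return integer depth.
#' @export
tree_depth <- function(t) max(node_depths_cpp(t$code))

#' Evaluate a program tree on feature data
#'
#' Recursively evaluates the arithmetic program: terminals read the feature
#' values, internal nodes apply their operator.  Division is protected
#' (`a / b = 1` when `|b| < 1e-9`) and every node output is clamped to
#' `[-1e150, 1e150]`, so the result is always finite.
#'
#' @param t a `gp_tree`.
#' @param x a length-`k` feature vector, or a `k x N` matrix (one sample per
#'   column) such as a projected expression matrix.
#' @return numeric scalar (vector input) or length-`N` vector (matrix input).
#' @examples
#' t <- gp_tree(c(-1L, 1L, 2L), 2)   # (add x1 x2)
#' eval_tree(t, c(2, 3))             # 5
#' @export
eval_tree <- function(t, x) {
  stopifnot(inherits(t, "gp_tree"))
  vec <- is.null(dim(x))
  X <- if (vec) matrix(as.numeric(x), ncol = 1L) else x
  if (nrow(X) < t$n_features && max(t$code) > nrow(X))
    stopf("terminal index %d out of range for %d features", max(t$code), nrow(X))
  out <- eval_prefix_cpp(t$code, X)
  if (vec) out[[1L]] else out
}

#' Classify samples with a program tree
#'
#' The signed program output is thresholded at zero: output `>= 0` is the
#' positive class (1), otherwise 0.
#'
#' @inheritParams eval_tree
#' @return integer 0/1 scalar or vector.
#' @export
classify <- function(t, x) {
  as.integer(eval_tree(t, x) >= 0)
}

# --- random growth -----------------------------------------------------------

# Append a random subtree in prefix order to buffer env `bufenv`.
# method "full": operators until depth == target, then terminals.
# method "grow": terminals allowed from depth >= min_depth; forced terminal
# at depth == target; otherwise operator with probability 0.5.
grow_code <- function(k, target, min_depth, method) {
  buf <- integer(0L)
  rec <- function(depth) {
    make_leaf <-
      if (depth >= target) TRUE
      else if (depth < min_depth) FALSE
      else if (method == "full") FALSE
      else runif(1L) < 0.5
    if (make_leaf) {
      buf[[length(buf) + 1L]] <<- sample.int(k, 1L)
    } else {
      buf[[length(buf) + 1L]] <<- OP_CODES[[sample.int(4L, 1L)]]
      rec(depth + 1L)
      rec(depth + 1L)
    }
  }
  rec(0L)
  buf
}

#' Grow a random program tree
#'
#' Draws a tree with the "full" method (every leaf at the target depth) or
#' the "grow" method (leaves allowed anywhere between `min_depth` and
#' `max_depth`).  Randomness comes from the current RNG stream.
#'
#' @param k number of available terminal features.
#' @param max_depth target (full) or maximum (grow) depth.
#' @param min_depth no leaf is placed shallower than this (grow method).
#' @param method `"grow"` or `"full"`.
#' @return a `gp_tree`.
#' @export
grow_random_tree <- function(k, max_depth, min_depth = 0L,
                             method = c("grow", "full")) {
  method <- match.arg(method)
  stopifnot(k >= 1L, max_depth >= 0L, min_depth <= max_depth)
  gp_tree(grow_code(k, max_depth, min_depth, method), k)
}

# --- serialization -----------------------------------------------------------

#' @export
format.gp_tree <- function(x, ...) {
  code <- x$code
  i <- 0L
  rec <- function() {
    i <<- i + 1L
    c0 <- code[i]
    if (c0 > 0L) return(paste0("x", c0))
    op <- OP_NAMES[-c0]
    l <- rec(); r <- rec()
    paste0("(", op, " ", l, " ", r, ")")
  }
  rec()
}

#' @export
print.gp_tree <- function(x, ...) {
  cat(sprintf("gp_tree: %d nodes, depth %d over %d features\n  %s\n",
              tree_size(x), tree_depth(x), x$n_features, format(x)))
  invisible(x)
}

#' Parse an S-expression into a program tree
#'
#' Inverse of `format()` on a `gp_tree`: parses strings such as
#' `"(div (add x3 x17) (sub x4 x9))"`, with 1-based terminal indices.
#'
#' @param text S-expression string.
#' @param n_features number of features terminals may index; defaults to the
#'   largest index seen.
#' @return a `gp_tree`.
#' @export
parse_tree <- function(text, n_features = NULL) {
  toks <- strsplit(gsub("([()])", " \\1 ", text), "[[:space:]]+")[[1L]]
  toks <- toks[nzchar(toks)]
  i <- 0L
  rec <- function() {
    i <<- i + 1L
    tk <- toks[i]
    if (is.na(tk)) stopf("unexpected end of expression")
    if (tk == "(") {
      i <<- i + 1L
      op <- match(toks[i], OP_NAMES)
      if (is.na(op)) stopf("unknown operator '%s'", toks[i])
      l <- rec(); r <- rec()
      i <<- i + 1L
      if (toks[i] != ")") stopf("expected ')' near token %d", i)
      c(OP_CODES[[op]], l, r)
    } else {
      if (!grepl("^x[0-9]+$", tk)) stopf("bad terminal '%s'", tk)
      as.integer(sub("^x", "", tk))
    }
  }
  code <- rec()
  if (i != length(toks)) stopf("trailing tokens in expression")
  if (is.null(n_features)) n_features <- max(code)
  gp_tree(code, n_features)
}
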