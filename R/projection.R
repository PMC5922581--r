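#' Build a seeded random projection matrix
#'
#' Constructs the `k x d` random matrix `R` used to map `d`-dimensional
#' expression profiles through the origin into a `k`-dimensional
#' (`k << d`) latent space, `X_rp = R %*% X`.  The default scheme draws
#' standard-normal entries and rescales every column of `R` to unit
#' Euclidean length; a sparse Achlioptas-style scheme with entries
#' `sqrt(3/k) * {+1, 0, -1}` (probabilities 1/6, 2/3, 1/6) is provided as a
#' cheaper alternative.  The matrix is fully reproducible from
#' `(d, k, seed, scheme)` and is independent of any data, so the same `R`
#' can be applied to training and test samples without leakage.
#'
#' @param d source dimensionality (number of features); `d > k`.
#' @param k target dimensionality.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @param scheme `"gaussian_unit_columns"` (default) or `"sparse_achlioptas"`.
#' @return a `projection_matrix`: a `k x d` numeric matrix with attributes
#'   `seed` and `scheme`.
#' @examples
#' p <- build_projection(d = 200, k = 10, seed = 7)
#' range(sqrt(colSums(p^2)))   # unit columns
#' @export
build_projection <- function(d, k, seed,
                             scheme = c("gaussian_unit_columns", "sparse_achlioptas")) {
  scheme <- match.arg(scheme)
  d <- as.integer(d); k <- as.integer(k)
  if (is.na(k) || k < 1L) stopf("k must be a positive integer, got %s", k)
  if (is.na(d) || k >= d)
    stopf("target dimension k (%d) must be smaller than source dimension d (%s)", k, d)
  R <- with_seed(seed, {
    if (scheme == "gaussian_unit_columns") {
      m <- matrix(rnorm(k * d), k, d)
      m / rep(sqrt(colSums(m^2)), each = k)
    } else {
      m <- matrix(sample(c(-1, 0, 0, 0, 0, 1), k * d, replace = TRUE), k, d)
      m * sqrt(3 / k)
    }
  })
  rownames(R) <- paste0("RP_", seq_len(k))
  attr(R, "seed") <- as.integer(seed)
  attr(R, "scheme") <- scheme
  class(R) <- c("projection_matrix", class(R))
  R
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat(sprintf("projection_matrix: k = %d, d = %d, scheme = %s, seed = %d\n",
              nrow(x), ncol(x), attr(x, "scheme"), attr(x, "seed")))
  invisible(x)
}

#' Project an expression matrix into the random latent space
#'
#' Computes `R %*% X`: `k` constructed features for every sample.  The
#' operation is linear and acts column-wise, so projecting the concatenation
#' of two sample sets equals concatenating their projections — this is what
#' makes applying one `R` to both the training and the test fold legitimate.
#' No `sqrt(d/k)` rescaling is applied.
#'
#' @param m expression matrix, `d` features x `N` samples.
#' @param p a [build_projection()] result with `ncol(p) == nrow(m)`.
#' @return expression matrix of `k` constructed features (`RP_1 .. RP_k`)
#'   x `N` samples.
#' @export
project <- function(m, p) {
  if (!inherits(p, "projection_matrix")) stopf("p must be a projection_matrix")
  if (ncol(p) != nrow(m))
    stopf("dimension mismatch: projection is %d x %d but matrix has %d features",
          nrow(p), ncol(p), nrow(m))
  out <- unclass(p) %*% m
  rownames(out) <- paste0("RP_", seq_len(nrow(out)))
  colnames(out) <- colnames(m)
  out
}

#' Write a projection matrix to delimited text
#'
#' The first line is a comment header recording `(k, d, seed, scheme)`;
#' the remaining lines are the matrix at 17 significant digits.
#'
#' @param p a `projection_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_projection <- function(p, path) {
  stopifnot(inherits(p, "projection_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#rpgp_projection\tk=%d\td=%d\tseed=%d\tscheme=%s",
                     nrow(p), ncol(p), attr(p, "seed"), attr(p, "scheme")), con)
  writeLines(vapply(seq_len(nrow(p)), function(i)
    paste(sprintf("%.17g", p[i, ]), collapse = "\t"), character(1L)), con)
  invisible(path)
}

#' Read a projection matrix written by [write_projection()]
#'
#' @param path file path.
#' @return a `projection_matrix`.
#' @export
read_projection <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#rpgp_projection")) stopf("%s: not a projection file", path)
  kv <- strsplit(strsplit(hdr, "\t")[[1L]][-1L], "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, character(1L), 2L),
                          vapply(kv, `[`, character(1L), 1L))
  vals <- as.matrix(utils::read.table(path, skip = 1L, sep = "\t"))
  dimnames(vals) <- list(paste0("RP_", seq_len(nrow(vals))), NULL)
  stopifnot(nrow(vals) == as.integer(meta[["k"]]),
            ncol(vals) == as.integer(meta[["d"]]))
  attr(vals, "seed") <- as.integer(meta[["seed"]])
  attr(vals, "scheme") <- meta[["scheme"]]
  class(vals) <- c("projection_matrix", class(vals))
  vals
}
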