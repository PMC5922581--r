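#' Construct and validate an expression matrix
#'
#' An expression matrix in rpgp is a plain numeric matrix of `d` features
#' (rows) by `N` samples (columns) with unique feature identifiers as row
#' names and unique sample identifiers as column names.  All consumers in the
#' package (projection, the GP classifier, the harness) expect this
#' orientation; on-disk files may be stored either way and are reoriented by
#' [read_expression()] according to an explicit flag, never by guessing.
#'
#' @param values numeric matrix or something coercible to one.
#' @param feature_ids,sample_ids character vectors of unique identifiers; if
#'   omitted, the dimnames of `values` are used.
#' @return a validated numeric matrix (features x samples) with dimnames.
#' @examples
#' m <- expression_matrix(matrix(rnorm(6), 3, 2),
#'                        feature_ids = c("g1", "g2", "g3"),
#'                        sample_ids  = c("s1", "s2"))
#' @export
expression_matrix <- function(values, feature_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(nrow(values)))
  if (is.null(sample_ids))  sample_ids  <- paste0("s", seq_len(ncol(values)))
  rownames(values) <- as.character(feature_ids)
  colnames(values) <- as.character(sample_ids)
  validate_expression(values)
  values
}

#' Validate an expression matrix
#'
#' Checks the invariants required throughout the package: at least one
#' feature, at least two samples, all values finite, and unique feature and
#' sample identifiers.
#'
#' @param m numeric matrix, features x samples.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stopf("expression data must be a numeric matrix")
  if (nrow(m) < 1L) stopf("expression matrix needs at least 1 feature")
  if (ncol(m) < 2L) stopf("expression matrix needs at least 2 samples")
  if (anyNA(m) || !all(is.finite(m)))
    stopf("expression matrix contains missing or non-finite values")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stopf("feature identifiers missing or duplicated")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stopf("sample identifiers missing or duplicated")
  invisible(m)
}

#' Read a delimited expression matrix
#'
#' Reads a delimited text file with a header row and an identifier first
#' column into a features x samples matrix.  The on-disk orientation is
#' stated explicitly by the caller: `"features_in_rows"` files are returned
#' as stored, `"samples_in_rows"` files are transposed after reading.  The
#' orientation flag only changes axis interpretation, never values.
#'
#' Missing cells (`NA` or empty) are a hard error unless `impute = TRUE`, in
#' which case they are replaced by the mean of the non-missing values of
#' their feature (computed after reorientation).
#'
#' @param path path to the file.
#' @param orientation `"features_in_rows"` (default) or `"samples_in_rows"`.
#' @param delimiter field separator, tab by default.
#' @param impute replace missing cells by the per-feature mean?
#' @return numeric matrix, features x samples, with identifiers as dimnames.
#' @seealso [write_expression()] for the exact-round-trip writer.
#' @export
read_expression <- function(path,
                            orientation = c("features_in_rows", "samples_in_rows"),
                            delimiter = "\t", impute = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delimiter,
                      check.names = FALSE, colClasses = "character",
                      quote = "\"", comment.char = ""),
    error = function(e) stopf("malformed table in %s: %s", path, conditionMessage(e)))
  if (ncol(raw) < 2L) stopf("%s: need an id column plus at least one data column", path)
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stopf("%s: duplicate row identifiers (e.g. '%s')", path, ids[duplicated(ids)][1L])
  cols <- colnames(raw)[-1L]
  if (anyDuplicated(cols))
    stopf("%s: duplicate column identifiers (e.g. '%s')", path, cols[duplicated(cols)][1L])
  vals <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L,
                 dimnames = list(ids, cols))
  for (j in seq_along(cols)) {
    cell <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is.na(cell) & !(trimws(cell) %in% c("NA", "")))
    if (length(bad))
      stopf("%s: non-numeric value '%s' at row '%s', column '%s'",
            path, cell[bad[1L]], ids[bad[1L]], cols[j])
    vals[, j] <- num
  }
  if (orientation == "samples_in_rows") vals <- t(vals)
  if (anyNA(vals)) {
    if (!impute)
      stopf("%s: missing values present; rerun with impute = TRUE for per-feature mean imputation", path)
    for (i in which(rowSums(is.na(vals)) > 0L)) {
      mu <- mean(vals[i, ], na.rm = TRUE)
      if (is.nan(mu)) stopf("%s: feature '%s' is entirely missing", path, rownames(vals)[i])
      vals[i, is.na(vals[i, ])] <- mu
    }
  }
  expression_matrix(vals)
}

#' Write an expression matrix to delimited text
#'
#' Values are written with 17 significant digits (`%.17g`) so that
#' `read_expression()` reproduces the matrix exactly, bit for bit.
#'
#' @param m numeric matrix, features x samples (see [expression_matrix()]).
#' @param path output path.
#' @param orientation on-disk layout to produce.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path,
                             orientation = c("features_in_rows", "samples_in_rows"),
                             delimiter = "\t") {
  orientation <- match.arg(orientation)
  validate_expression(m)
  out <- if (orientation == "features_in_rows") m else t(m)
  idname <- if (orientation == "features_in_rows") "feature_id" else "sample_id"
  header <- paste(c(idname, colnames(out)), collapse = delimiter)
  body <- vapply(seq_len(nrow(out)), function(i)
    paste(c(rownames(out)[i], sprintf("%.17g", out[i, ])), collapse = delimiter),
    character(1L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Construct a binary label vector
#'
#' Labels are stored as an integer 0/1 vector named by sample identifier,
#' with the name of the positive class kept as an attribute.  Exactly two
#' classes must be present.
#'
#' @param labels a vector of class labels (character, factor, or already 0/1).
#' @param positive_class the label mapped to 1; every other label maps to 0.
#' @param sample_ids sample identifiers aligned with `labels`.
#' @return an integer vector of class `label_vector`.
#' @examples
#' label_vector(c("SCC", "AC", "AC"), positive_class = "SCC",
#'              sample_ids = c("s1", "s2", "s3"))
#' @export
label_vector <- function(labels, positive_class, sample_ids = names(labels)) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L)
    stopf("labels must contain exactly 2 classes, found %d (%s)",
          length(lev), paste(utils::head(lev, 4L), collapse = ", "))
  positive_class <- as.character(positive_class)
  if (!positive_class %in% lev)
    stopf("positive class '%s' not among observed labels (%s)",
          positive_class, paste(lev, collapse = ", "))
  y <- as.integer(labels == positive_class)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_along(y))
  if (length(sample_ids) != length(y)) stopf("sample_ids length mismatch")
  if (anyDuplicated(sample_ids)) stopf("duplicate sample identifiers in labels")
  names(y) <- as.character(sample_ids)
  attr(y, "positive_class") <- positive_class
  class(y) <- "label_vector"
  y
}

#' @export
`[.label_vector` <- function(x, i) {
  out <- unclass(x)[i]
  attr(out, "positive_class") <- attr(x, "positive_class")
  class(out) <- "label_vector"
  out
}

#' @export
print.label_vector <- function(x, ...) {
  cat(sprintf("label_vector: %d samples, %d positive ('%s'), %d negative\n",
              length(x), sum(x == 1L), attr(x, "positive_class"), sum(x == 0L)))
  invisible(x)
}

#' Read a sample label file
#'
#' Expects a two-column delimited file with a header row: sample identifier,
#' then class label.  Exactly two distinct labels must occur; the one named
#' by `positive_class` is mapped to 1.
#'
#' @param path path to the label file.
#' @param positive_class label to treat as the positive (1) class.
#' @param delimiter field separator.
#' @return a [label_vector()].
#' @export
read_labels <- function(path, positive_class, delimiter = "\t") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) != 2L) stopf("%s: expected 2 columns (sample_id, label)", path)
  label_vector(tab[[2L]], positive_class = positive_class, sample_ids = tab[[1L]])
}

#' Write a sample label file
#'
#' @param y a [label_vector()].
#' @param path output path.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_labels <- function(y, path, delimiter = "\t") {
  stopifnot(inherits(y, "label_vector"))
  pos <- attr(y, "positive_class")
  lab <- ifelse(unclass(y) == 1L, pos, paste0("not_", pos))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("sample_id", "label", sep = delimiter),
               paste(names(y), lab, sep = delimiter)), con)
  invisible(path)
}

#' Check that labels align with an expression matrix
#'
#' The harness requires labels and samples in identical order; silent
#' reordering is never attempted.
#'
#' @param m expression matrix (features x samples).
#' @param y a [label_vector()].
#' @return invisibly `TRUE` if aligned, otherwise an error.
#' @export
assert_aligned <- function(m, y) {
  if (length(y) != ncol(m))
    stopf("alignment error: %d labels but %d samples", length(y), ncol(m))
  if (!identical(names(y), colnames(m)))
    stopf("alignment error: label sample_ids do not match matrix sample_ids in order")
  invisible(TRUE)
}

#' Read an ARFF expression file
#'
#' Convenience reader for Weka-style ARFF files whose attributes are numeric
#' features (one instance per row) plus one nominal class attribute.  The
#' numeric attributes become features, instances become samples.
#'
#' @param path ARFF file path.
#' @param positive_class if given and a nominal class attribute exists,
#'   labels are returned as well.
#' @return a list with elements `matrix` (features x samples) and `labels`
#'   (a [label_vector()] or `NULL`).
#' @export
read_arff_expression <- function(path, positive_class = NULL) {
  df <- foreign::read.arff(path)
  is_fac <- vapply(df, is.factor, logical(1L))
  labels <- NULL
  if (any(is_fac)) {
    cls <- df[[which(is_fac)[sum(is_fac)]]]   # last nominal attribute
    df <- df[!is_fac]
    if (!is.null(positive_class))
      labels <- label_vector(as.character(cls), positive_class,
                             sample_ids = paste0("s", seq_len(nrow(df))))
  }
  m <- expression_matrix(t(as.matrix(df)),
                         feature_ids = colnames(df),
                         sample_ids  = paste0("s", seq_len(nrow(df))))
  list(matrix = m, labels = labels)
}
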