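# Reading, writing and reshaping feature / phenotype tables.

#' Vectorize a square symmetric connectome matrix
#'
#' Connectome matrices are symmetric, so predictive models consume only the
#' strict upper triangle, flattened in row-major order. Edge names are built
#' from the node labels as `"nodeA-nodeB"`.
#'
#' @param m Square numeric matrix, symmetric within `tol` (relative to the
#'   largest absolute entry).
#' @param tol Relative symmetry tolerance.
#' @return Named numeric vector of length `n * (n - 1) / 2`.
#' @examples
#' m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
#' vectorize_symmetric(m)
#' @seealso [devectorize_symmetric()]
#' @export
vectorize_symmetric <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort("vectorize_symmetric() expects a square matrix")
  }
  n <- nrow(m)
  scale <- max(abs(m), 1)
  asym <- abs(m - t(m))
  if (max(asym) > tol * scale) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "matrix is not symmetric: |m[%d,%d] - m[%d,%d]| = %.3g exceeds tolerance",
      ij[1], ij[2], ij[2], ij[1], max(asym)
    ))
  }
  labels <- rownames(m) %||% colnames(m) %||% sprintf("n%03d", seq_len(n))
  ut <- which(upper.tri(m), arr.ind = TRUE)
  ord <- order(ut[, "row"], ut[, "col"]) # row-major
  ut <- ut[ord, , drop = FALSE]
  v <- m[ut]
  names(v) <- paste(labels[ut[, "row"]], labels[ut[, "col"]], sep = "-")
  v
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_symmetric()]: places the edge vector back into the
#' strict upper and lower triangles (row-major order) with `diag` on the
#' diagonal.
#'
#' @param v Edge vector of length `n * (n - 1) / 2`.
#' @param diag Value for the diagonal (default 0).
#' @return A symmetric `n x n` matrix.
#' @export
devectorize_symmetric <- function(v, diag = 0) {
  e <- length(v)
  n <- (1 + sqrt(1 + 8 * e)) / 2
  if (n != round(n)) {
    abort(sprintf("length %d is not a valid edge count n*(n-1)/2", e))
  }
  n <- as.integer(round(n))
  m <- matrix(diag, n, n)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  ut <- ut[order(ut[, "row"], ut[, "col"]), , drop = FALSE]
  m[ut] <- v
  m[ut[, c(2, 1)]] <- v
  if (!is.null(names(v))) {
    labels <- unique(unlist(strsplit(names(v), "-", fixed = TRUE)))
    if (length(labels) == n) dimnames(m) <- list(labels, labels)
  }
  m
}

#' Flag phenotype outliers beyond k standard deviations
#'
#' Supplementary variant of the analysis: subjects whose target value deviates
#' from the mean by more than `k` standard deviations (mean and sd computed
#' once on the full vector) are dropped before any splitting. The primary
#' analysis performs no outlier rejection, so this filter is opt-in and is
#' never applied inside cross-validation folds.
#'
#' @param y Numeric target vector with at least 3 values.
#' @param k Threshold in standard deviations (default 3).
#' @return A list with `keep` (integer indices retained), `dropped` (indices
#'   removed), and a one-row `report` tibble (n, n_dropped, mean, sd, k).
#' @examples
#' filter_outliers(c(0, 0, 0, 0, 100))
#' @export
filter_outliers <- function(y, k = 3) {
  stopifnot(is.numeric(y), k > 0)
  if (length(y) < 3) abort("filter_outliers() needs at least 3 values")
  mu <- mean(y)
  s <- sd(y)
  if (s == 0) {
    warn("target has zero variance; no outliers removed")
    keep <- seq_along(y)
  } else {
    keep <- which(abs(y - mu) <= k * s)
  }
  list(
    keep = keep,
    dropped = setdiff(seq_along(y), keep),
    report = tibble::tibble(
      n = length(y), n_dropped = length(y) - length(keep),
      mean = mu, sd = s, k = k
    )
  )
}

#' Read / write feature and phenotype tables
#'
#' Tables are delimited text with a header row and the subject id in the first
#' column (`subject_id`). Tab is the default delimiter; comma is accepted on
#' read and available on write.
#'
#' @param path File path.
#' @param delim Field delimiter (`"\t"` or `","`).
#' @return `read_feature_table()` / `read_phenotype_table()` return a tibble
#'   whose first column is `subject_id`; the writers return `path` invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_feature_table <- function(path, delim = "\t") {
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "subject_id"
  x$subject_id <- as.character(x$subject_id)
  if (anyDuplicated(x$subject_id)) abort("duplicate subject ids in feature table")
  if (anyNA(x)) abort(sprintf("missing values in feature table '%s'", path))
  x
}

#' @rdname table_io
#' @param x Table to write (tibble with `subject_id` first).
#' @export
write_feature_table <- function(x, path, delim = "\t") {
  stopifnot(is.data.frame(x))
  readr::write_delim(x, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_phenotype_table <- function(path, delim = "\t") {
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "subject_id"
  x$subject_id <- as.character(x$subject_id)
  if (anyDuplicated(x$subject_id)) abort("duplicate subject ids in phenotype table")
  x
}

#' @rdname table_io
#' @export
write_phenotype_table <- function(x, path, delim = "\t") {
  stopifnot(is.data.frame(x))
  readr::write_delim(x, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Join a phenotype column onto a feature table
#'
#' Inner join on `subject_id`, preserving the subject order of the feature
#' table. Subjects with a missing value in the requested target are dropped
#' (with a message), since a subject without that phenotype cannot enter that
#' phenotype's models.
#'
#' @param features Feature table (tibble, `subject_id` first column).
#' @param phenotypes Phenotype table (tibble, `subject_id` plus target columns).
#' @param target Name of the target column to keep.
#' @return A list with `features` (rows restricted to usable subjects) and `y`
#'   (numeric target aligned with them).
#' @export
join_feature_phenotype <- function(features, phenotypes, target) {
  stopifnot(is.data.frame(features), is.data.frame(phenotypes))
  if (!target %in% names(phenotypes)) {
    abort(sprintf("target '%s' not found in phenotype table", target))
  }
  idx <- match(features$subject_id, as.character(phenotypes$subject_id))
  yv <- phenotypes[[target]][idx]
  ok <- !is.na(idx) & !is.na(yv)
  n_drop <- sum(!ok)
  if (n_drop > 0) {
    inform(sprintf(
      "dropping %d subject(s) without a '%s' value", n_drop, target
    ))
  }
  y <- as.numeric(yv[ok])
  if (length(unique(y)) < 2) {
    abort(sprintf("target '%s' has fewer than 2 distinct values after join", target))
  }
  list(features = features[ok, , drop = FALSE], y = y)
}
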