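# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. `seed = NULL` leaves the RNG alone.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible child seed from a master seed
#'
#' Curve runs need one independent, reproducible random stream per
#' (phenotype, metric, sample size, shuffle) cell so that any cell can be
#' recomputed in isolation and records can be aggregated in any order. Child
#' seeds are derived by folding the integer coordinates of the cell into the
#' master seed with a Lehmer-style multiplicative mix modulo the Mersenne
#' prime 2^31 - 1, which keeps every seed a valid 32-bit integer.
#'
#' @param seed Master seed (single integer-valued number).
#' @param ... Integer coordinates identifying the cell (any number of them).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(42, 3, 125, 7)
#' @export
derive_seed <- function(seed, ...) {
  ks <- c(...)
  stopifnot(length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1
  x <- (abs(as.numeric(seed)) %% m)
  for (k in c(1, as.numeric(ks))) {
    x <- (x * 48271 + abs(k) + 1) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

# Pearson correlation that returns NA instead of erroring/warning on
# zero-variance input.
safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

# Coerce a feature table (tibble with subject-id first column) or bare matrix
# to a numeric matrix plus subject ids.
as_feature_matrix <- function(x, id_col = "subject_id") {
  if (is.matrix(x)) {
    ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
    return(list(X = x, ids = ids))
  }
  if (!is.data.frame(x)) {
    abort("features must be a data frame or a numeric matrix")
  }
  if (id_col %in% names(x)) {
    ids <- as.character(x[[id_col]])
    X <- as.matrix(x[setdiff(names(x), id_col)])
  } else {
    ids <- as.character(seq_len(nrow(x)))
    X <- as.matrix(x)
  }
  storage.mode(X) <- "double"
  list(X = X, ids = ids)
}

# Extract a response vector aligned with `ids` from a vector or a two-column
# phenotype table (subject_id, value) / (subject_id, <name>).
as_response <- function(y, ids, value_col = NULL) {
  if (is.numeric(y) && is.null(dim(y))) {
    if (length(y) != length(ids)) {
      abort(sprintf(
        "response length (%d) does not match number of subjects (%d)",
        length(y), length(ids)
      ))
    }
    return(as.numeric(y))
  }
  if (is.data.frame(y)) {
    if (!"subject_id" %in% names(y)) {
      abort("phenotype table must contain a 'subject_id' column")
    }
    vcol <- value_col %||% setdiff(names(y), "subject_id")[1]
    idx <- match(ids, as.character(y$subject_id))
    if (anyNA(idx)) {
      abort("phenotype table is missing some subjects present in the features")
    }
    return(as.numeric(y[[vcol]][idx]))
  }
  abort("response must be a numeric vector or a phenotype table")
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
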