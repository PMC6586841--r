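# Internal helpers shared across modules.

# Coerce a data frame / tibble / matrix / sparse Matrix to a dense numeric
# matrix of observations x features.  Non-numeric columns are an error, as is
# any non-finite entry: downstream triplet distances are meaningless with
# missing values, so the policy is a hard failure, never silent imputation.
as_feature_matrix <- function(x, arg = "data", require_finite = TRUE) {
  if (inherits(x, "sparseMatrix")) {
    x <- as.matrix(x)
  }
  if (is.data.frame(x)) {
    bad <- !vapply(x, is.numeric, logical(1))
    if (any(bad)) {
      abort(sprintf(
        "All columns of `%s` must be numeric; offending columns: %s",
        arg, paste(names(x)[bad], collapse = ", ")
      ))
    }
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix or data frame.", arg))
  }
  storage.mode(x) <- "double"
  if (require_finite && !all(is.finite(x))) {
    n_bad <- sum(!is.finite(x))
    abort(sprintf(
      "`%s` contains %d non-finite value(s) (NA/NaN/Inf); refusing to impute.",
      arg, n_bad
    ))
  }
  x
}

check_positive_number <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single %s number, got %s.",
      name, if (strict) "positive" else "non-negative",
      paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    x == as.integer(x) && x >= min
  if (!ok) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  With seed = NULL the current stream
# is used (and advanced).
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
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
  set.seed(seed)
  force(code)
}

# Derive a stage-specific child seed from the active RNG stream; keeps every
# stochastic stage on a deterministic path from one global seed while staying
# below .Machine$integer.max.
draw_seed <- function() {
  sample.int(.Machine$integer.max - 1L, 1L)
}
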