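# Approximate k-nearest-neighbour retrieval over dataset rows, backed by
# Annoy's random-projection trees.  Neighbour lists drive triplet mining:
# positives are drawn from a row's list, negatives from outside it, so the
# quality of the lists bounds how faithfully local structure can be learned.

#' Default neighbourhood size for triplet mining
#'
#' The number of nearest neighbours retained per observation.  Around 0.5-1%
#' of the number of observations gives the most accurate embeddings, and
#' accuracy is broadly stable across a wide band of k, so the default takes
#' 1% of `n_obs`, clamped to at least 2 and at most `min(150, n_obs - 2)`.
#' The upper cap keeps neighbour-list memory linear on million-row inputs
#' while staying inside the stable band.
#'
#' @param n_obs Number of observations; must be at least 3.
#' @return A single integer k.
#' @export
#' @examples
#' default_k(10000) # 100
#' default_k(100)   # 2
default_k <- function(n_obs) {
  n_obs <- check_count(n_obs, "n_obs")
  if (n_obs < 3) abort("`n_obs` must be at least 3.")
  k <- round(0.01 * n_obs)
  as.integer(max(2L, min(k, 150L, n_obs - 2L)))
}

#' Build an approximate k-nearest-neighbour index
#'
#' Constructs a forest of random-projection trees (Annoy) over the rows of
#' `x` under Euclidean distance and extracts, for every row, its `k`
#' approximate nearest neighbours.  A row is never its own neighbour.  Ties
#' in distance are broken towards the lower row index, making results
#' deterministic for a fixed seed.
#'
#' @param x Numeric matrix or data frame (observations x features).
#' @param k Neighbours retained per row; defaults to [default_k()] of the
#'   row count.  Must be `< n_obs`.
#' @param n_trees Number of random-projection trees (default 50).  More trees
#'   raise recall at the cost of build time.
#' @param seed Optional integer seed for the tree construction.
#' @param search_k Search breadth at query time; `-1` (default) uses Annoy's
#'   convention of `n_trees * k`.  Larger values raise recall.
#' @return An object of class `neighbour_index`: a list with the integer
#'   matrix `idx` (`n_obs` x `k`, row i holding the ordered neighbour row
#'   indices of i), plus `k`, `n_trees`, `metric`, and `n_obs`.
#' @export
build_index <- function(x, k = NULL, n_trees = 50, seed = NULL, search_k = -1) {
  m <- as_feature_matrix(x, arg = "x")
  n <- nrow(m)
  k <- if (is.null(k)) default_k(n) else check_count(k, "k")
  if (k >= n) {
    abort(sprintf("`k` (%d) must be smaller than the number of rows (%d).", k, n))
  }
  n_trees <- check_count(n_trees, "n_trees")
  ann <- new(RcppAnnoy::AnnoyEuclidean, ncol(m))
  if (!is.null(seed)) ann$setSeed(as.integer(seed))
  for (i in seq_len(n)) {
    ann$addItem(i - 1L, m[i, ])
  }
  ann$build(n_trees)

  idx <- matrix(NA_integer_, n, k)
  # Ask for k+1 candidates since the query point itself is normally returned
  # first; over-fetch a little so an approximate miss of `self` still leaves
  # k usable neighbours.
  n_fetch <- min(n, k + 2L)
  for (i in seq_len(n)) {
    res <- ann$getNNsByItemList(i - 1L, n_fetch, as.integer(search_k), TRUE)
    if (length(res$item) < n_fetch) {
      # early-terminated search returned too few candidates; retry exhaustively
      res <- ann$getNNsByItemList(i - 1L, n_fetch, n * n_trees, TRUE)
    }
    items <- res$item + 1L
    d <- res$distance
    keep <- items != i
    items <- items[keep]
    d <- d[keep]
    ord <- order(d, items)
    idx[i, ] <- items[ord][seq_len(k)]
  }
  structure(
    list(idx = idx, k = k, n_trees = n_trees, metric = "euclidean", n_obs = n),
    class = "neighbour_index"
  )
}

#' @rdname build_index
#' @param ... Unused.
#' @method print neighbour_index
#' @export
print.neighbour_index <- function(x, ...) {
  cat(sprintf(
    "<neighbour_index> %d observations, k = %d, %d trees, %s metric\n",
    x$n_obs, x$k, x$n_trees, x$metric
  ))
  invisible(x)
}
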