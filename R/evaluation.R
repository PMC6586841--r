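# Quantitative structure-preservation protocols.
#
# The central question for any embedding is whether inter-cluster geometry
# survives the projection.  The protocol here: average each cluster to its
# centroid, form the Euclidean inter-centroid distance matrix in the original
# and the embedded space, and measure the Pearson correlation between the two
# matrices' upper triangles with a Mantel permutation test.  Repeating over
# random subsamples yields a distribution of correlations per method, which
# distributions are compared with a two-tailed t-test.

#' Inter-centroid distance matrix
#'
#' Each cluster's centroid is the arithmetic mean of its rows; the result is
#' the symmetric matrix of pairwise Euclidean distances between centroids,
#' with clusters in sorted label order (so the matrix is invariant to the
#' order the rows arrive in).
#'
#' @param x Numeric matrix or data frame (observations x features).
#' @param labels Cluster labels, one per row; at least 3 distinct values
#'   (the Mantel test needs off-diagonal degrees of freedom).
#' @return Symmetric numeric matrix with zero diagonal and the sorted
#'   cluster labels as dimnames.
#' @export
#' @examples
#' x <- matrix(c(0, 2, 10, 12, 20, 22), ncol = 1)
#' centroid_distances(x, rep(c("a", "b", "c"), each = 2))
centroid_distances <- function(x, labels) {
  m <- as_feature_matrix(x, arg = "x")
  labels <- as.character(labels)
  if (length(labels) != nrow(m)) {
    abort(sprintf(
      "`labels` has length %d but `x` has %d rows.", length(labels), nrow(m)
    ))
  }
  lev <- sort(unique(labels))
  if (length(lev) < 3) {
    abort(sprintf(
      "Need at least 3 distinct clusters for centroid-distance analysis, got %d.",
      length(lev)
    ))
  }
  centroids <- rowsum(m, labels) / as.vector(table(labels)[lev])
  centroids <- centroids[lev, , drop = FALSE]
  d <- as.matrix(stats::dist(centroids))
  dimnames(d) <- list(lev, lev)
  d
}

upper_tri_values <- function(d) d[upper.tri(d)]

#' Mantel test between two centroid distance matrices
#'
#' Pearson correlation of the strictly-upper-triangle entries of the two
#' matrices, with a permutation p-value: rows and columns of the second
#' matrix are permuted simultaneously, and the two-sided p-value is
#' `(1 + #{|r_perm| >= |r_obs|}) / (1 + n_perm)` — never exactly zero.
#'
#' @param d1,d2 Symmetric distance matrices over the same clusters in the
#'   same order (at least 3 x 3), e.g. from [centroid_distances()].
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed for the permutations.
#' @return One-row tibble with `pcc`, `p_value`, `n_perm`, `n_clusters`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  d1 <- as.matrix(d1)
  d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2))) {
    abort("`d1` and `d2` must have identical dimensions.")
  }
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2))) {
    abort("`d1` and `d2` are over different cluster sets (dimnames differ).")
  }
  c_n <- nrow(d1)
  if (c_n < 3) abort("Mantel test needs at least 3 clusters.")
  v1 <- upper_tri_values(d1)
  v2 <- upper_tri_values(d2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    abort("Zero variance in a distance-matrix upper triangle; correlation undefined.")
  }
  r_obs <- stats::cor(v1, v2)
  n_perm <- check_count(n_perm, "n_perm")
  with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      p <- sample.int(c_n)
      r_p <- stats::cor(v1, upper_tri_values(d2[p, p]))
      if (abs(r_p) >= abs(r_obs)) hits <- hits + 1L
    }
    tibble(
      pcc = r_obs,
      p_value = (1 + hits) / (1 + n_perm),
      n_perm = n_perm,
      n_clusters = c_n
    )
  })
}

#' Structure-preservation benchmark over repeated subsamples
#'
#' For each of `n_subsamples` random subsamples (without replacement), each
#' embedder is applied to the subsampled data; the Mantel correlation is
#' computed between the inter-centroid distance matrix of the reference
#' space and that of each embedding.  Per-method correlation distributions
#' are summarised by their median and mean and compared pairwise with
#' two-tailed t-tests.  A subsample that loses a cluster entirely is
#' resampled (with a message), up to `max_retries` attempts.
#'
#' @param data Numeric matrix or data frame the embedders consume.
#' @param labels Cluster labels, one per row.
#' @param embedders Named list of functions; each takes the subsampled data
#'   matrix and returns an embedding (matrix or data frame with one row per
#'   input row).  A fitted model's transform, t-SNE, PCA, etc. all fit this
#'   contract.
#' @param n_subsamples Number of subsamples (default 100).
#' @param subsample_size Rows per subsample, drawn without replacement
#'   (default 10000; capped at `n_obs`).
#' @param reference Optional matrix/data frame whose centroid geometry is the
#'   ground truth (e.g. generative 2-D coordinates of a lifted synthetic
#'   dataset); defaults to `data` itself.
#' @param n_perm Mantel permutations per subsample (default 99; the p-values
#'   are ancillary here, the correlations are the endpoint).
#' @param max_retries Resampling cap per subsample (default 100).
#' @param seed Optional seed.
#' @return An object of class `structure_report`: list with tibbles
#'   `per_subsample` (`subsample`, `method`, `pcc`, `p_value`), `summary`
#'   (`method`, `median_pcc`, `mean_pcc`), and `comparison` (pairwise
#'   `t_statistic`, `p_value`).
#' @export
structure_benchmark <- function(data, labels, embedders, n_subsamples = 100,
                                subsample_size = 10000, reference = NULL,
                                n_perm = 99, max_retries = 100, seed = NULL) {
  x <- as_feature_matrix(data, arg = "data")
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x))
  if (is.null(names(embedders)) || any(names(embedders) == "")) {
    abort("`embedders` must be a fully named list of functions.")
  }
  ref <- if (is.null(reference)) x else as_feature_matrix(reference, "reference")
  stopifnot(nrow(ref) == nrow(x))
  n <- nrow(x)
  subsample_size <- min(check_count(subsample_size, "subsample_size"), n)

  with_seed(seed, {
    rows <- vector("list", n_subsamples * length(embedders))
    slot <- 1L
    for (s in seq_len(n_subsamples)) {
      idx <- NULL
      for (try in seq_len(max_retries)) {
        cand <- sample.int(n, subsample_size)
        if (length(unique(labels[cand])) >= 3 &&
            length(unique(labels[cand])) == length(unique(labels))) {
          idx <- cand
          break
        }
        message(sprintf("subsample %d lost a cluster; resampling (attempt %d)", s, try))
      }
      if (is.null(idx)) {
        abort(sprintf(
          "Subsample %d kept losing clusters after %d attempts; reduce cluster imbalance or raise `subsample_size`.",
          s, max_retries
        ))
      }
      d_ref <- centroid_distances(ref[idx, , drop = FALSE], labels[idx])
      for (meth in names(embedders)) {
        emb <- as_feature_matrix(embedders[[meth]](x[idx, , drop = FALSE]),
                                 arg = sprintf("embedders$%s", meth))
        stopifnot(nrow(emb) == length(idx))
        d_emb <- centroid_distances(emb, labels[idx])
        mt <- mantel_test(d_ref, d_emb, n_perm = n_perm, seed = draw_seed())
        rows[[slot]] <- tibble(subsample = s, method = meth,
                               pcc = mt$pcc, p_value = mt$p_value)
        slot <- slot + 1L
      }
    }
    per_subsample <- dplyr::bind_rows(rows)
    summary <- per_subsample |>
      dplyr::group_by(.data$method) |>
      dplyr::summarise(median_pcc = stats::median(.data$pcc),
                       mean_pcc = mean(.data$pcc), .groups = "drop")
    methods <- names(embedders)
    comp <- list()
    if (length(methods) >= 2 && n_subsamples >= 2) {
      pairs <- utils::combn(methods, 2, simplify = FALSE)
      comp <- purrr::map(pairs, function(pr) {
        a <- per_subsample$pcc[per_subsample$method == pr[1]]
        b <- per_subsample$pcc[per_subsample$method == pr[2]]
        tt <- stats::t.test(a, b, alternative = "two.sided")
        tibble(method1 = pr[1], method2 = pr[2],
               t_statistic = unname(tt$statistic), p_value = tt$p.value)
      })
    }
    structure(
      list(per_subsample = per_subsample, summary = summary,
           comparison = dplyr::bind_rows(comp)),
      class = "structure_report"
    )
  })
}

#' @rdname structure_benchmark
#' @param x A structure report (print method).
#' @param ... Unused.
#' @method print structure_report
#' @export
print.structure_report <- function(x, ...) {
  cat("<structure_report>\n")
  print(x$summary)
  if (nrow(x$comparison)) {
    cat("pairwise two-tailed t-tests on the correlation distributions:\n")
    print(x$comparison)
  }
  invisible(x)
}

#' Out-of-sample extrapolation experiment
#'
#' How many observations does the parametric map need before out-of-sample
#' embeddings are class-faithful?  For each subset size and repeat: fit an
#' embedding on a random subset, train a classifier on the subset embeddings
#' and their labels, embed the held-out rows with the fitted model's
#' transform, and score the classifier's predictions against the held-out
#' labels (micro accuracy).
#'
#' @param data Numeric matrix or data frame.
#' @param labels Class labels, one per row.
#' @param subset_sizes Integer vector of training-subset sizes, all
#'   `< n_obs`.
#' @param repeats Repeats per size (default 10).
#' @param classifier Function `(x, y)` returning an object whose
#'   `predict(object, newx)` yields labels; default is a random forest
#'   ([ranger::ranger]).
#' @param seed Optional seed.
#' @param ... Passed to [triplet_embedding()] (e.g. `epochs`, `k`).
#' @return Tibble with columns `size`, `rep`, `accuracy`, and a list-column
#'   `confusion` of row-label x predicted-label contingency tables.
#' @export
extrapolation_experiment <- function(data, labels, subset_sizes, repeats = 10,
                                     classifier = NULL, seed = NULL, ...) {
  x <- as_feature_matrix(data, arg = "data")
  labels <- factor(labels)
  stopifnot(length(labels) == nrow(x))
  n <- nrow(x)
  subset_sizes <- vapply(subset_sizes, check_count, integer(1), name = "subset_sizes")
  if (max(subset_sizes) >= n) {
    abort("All `subset_sizes` must be smaller than the number of rows.")
  }
  classifier <- classifier %||% default_rf_classifier

  with_seed(seed, {
    grid <- expand.grid(size = subset_sizes, rep = seq_len(repeats))
    out <- purrr::pmap(grid, function(size, rep) {
      idx <- sample.int(n, size)
      fit <- triplet_embedding(x[idx, , drop = FALSE], seed = draw_seed(), ...)
      clf <- classifier(as.matrix(fit$embedding), droplevels(labels[idx]))
      emb_out <- predict(fit, x[-idx, , drop = FALSE])
      pred <- factor(predict(clf, as.matrix(emb_out)), levels = levels(labels))
      truth <- labels[-idx]
      tibble(
        size = size, rep = rep,
        accuracy = mean(pred == truth),
        confusion = list(table(truth = truth, predicted = pred))
      )
    })
    dplyr::bind_rows(out)
  })
}

# Default classifier for the extrapolation experiment: a random forest on
# the embedding coordinates.  Wrapped so any model obeying the
# fit/predict contract can be swapped in.
default_rf_classifier <- function(x, y) {
  df <- data.frame(x)
  df$.class <- y
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = 200, num.threads = 1, seed = draw_seed()
  )
  structure(list(fit = fit, feat = setdiff(names(df), ".class")),
            class = "rf_embedding_classifier")
}

#' @export
predict.rf_embedding_classifier <- function(object, newdata, ...) {
  df <- data.frame(newdata)
  names(df) <- object$feat
  as.character(predict(object$fit, data = df, num.threads = 1)$predictions)
}

#' Run-to-run stability of the embedding's cluster geometry
#'
#' Fits `n_runs` models with independent seeds and, for every pair of runs,
#' computes the Mantel correlation between the label-centroid distance
#' matrices of the two embeddings.  High minimum pairwise correlation means
#' the stochastic ingredients (approximate KNN, weight initialisation,
#' triplet sampling, dropout) do not change the recovered structure.
#'
#' @param data Numeric matrix or data frame.
#' @param labels Cluster labels, one per row (at least 3 clusters).
#' @param n_runs Number of independently seeded fits (default 10).
#' @param seed Optional seed from which the per-run seeds are derived.
#' @param ... Passed to [triplet_embedding()].
#' @return List with `pairwise` (symmetric `n_runs` x `n_runs` matrix of
#'   Mantel correlations, unit diagonal), `min_pcc`, and `models` (the
#'   fitted models).
#' @export
stability_across_runs <- function(data, labels, n_runs = 10, seed = NULL, ...) {
  n_runs <- check_count(n_runs, "n_runs", min = 2L)
  x <- as_feature_matrix(data, arg = "data")
  with_seed(seed, {
    seeds <- replicate(n_runs, draw_seed())
    models <- purrr::map(seeds, function(s) triplet_embedding(x, seed = s, ...))
    mats <- purrr::map(models, function(m) centroid_distances(as.matrix(m$embedding), labels))
    pw <- diag(1, n_runs)
    for (i in seq_len(n_runs - 1)) {
      for (j in seq(i + 1, n_runs)) {
        r <- stats::cor(upper_tri_values(mats[[i]]), upper_tri_values(mats[[j]]))
        pw[i, j] <- pw[j, i] <- r
      }
    }
    list(pairwise = pw, min_pcc = min(pw[upper.tri(pw)]), models = models)
  })
}

#' Hopkins clustering-tendency statistic
#'
#' Compares nearest-neighbour distances from `m` uniform probe points (`u`)
#' against nearest-neighbour distances from `m` sampled data points to the
#' rest of the data (`w`): `H = sum(u) / (sum(u) + sum(w))`.  Spatially
#' random data gives H near 0.5; strongly clustered data approaches 1.
#' Used here to verify that embedding pure noise does not fabricate
#' clusters.
#'
#' For two-dimensional data the probes are drawn uniformly over the convex
#' hull of the point cloud rather than its bounding box.  Embeddings are
#' defined only up to rigid motions, and bounding-box probing is not
#' rotation invariant — a uniform square rotated by 45 degrees is scored as
#' strongly clustered under the box convention purely from its empty box
#' corners, which would make the statistic useless for judging embeddings.
#' Hull probing is
#' isometry-robust while still driving H towards 1 for genuinely clustered
#' point sets (compact clusters separated by empty interior space).  For
#' `d > 2` (where hull sampling is impractical) the bounding box is used
#' and the same caveat applies.
#'
#' @param x Numeric matrix or data frame.
#' @param m Number of probe points (default `min(n - 1, ceiling(0.1 * n))`).
#' @param seed Optional seed.
#' @return A single number in (0, 1).
#' @export
hopkins_statistic <- function(x, m = NULL, seed = NULL) {
  x <- as_feature_matrix(x, arg = "x")
  n <- nrow(x)
  d <- ncol(x)
  if (n < 3) abort("Need at least 3 rows.")
  m <- if (is.null(m)) min(n - 1L, ceiling(0.1 * n)) else check_count(m, "m")
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  with_seed(seed, {
    box_probes <- function(mm) {
      matrix(sapply(seq_len(d), function(j) stats::runif(mm, lo[j], hi[j])),
             mm, d)
    }
    if (d == 2) {
      hull <- grDevices::chull(x)
      hx <- x[hull, 1]
      hy <- x[hull, 2]
      probes <- matrix(numeric(0), 0, 2)
      while (nrow(probes) < m) {
        cand <- box_probes(3 * m)
        probes <- rbind(probes, cand[points_in_polygon(cand, hx, hy), ,
                                     drop = FALSE])
      }
      probes <- probes[seq_len(m), , drop = FALSE]
    } else {
      probes <- box_probes(m)
    }
    samp <- sample.int(n, m)
    # nearest-neighbour distances, brute force (one m x n distance block)
    nn_dist <- function(a, b, exclude_self_idx = NULL) {
      dd <- outer(rowSums(a^2), rep(1, nrow(b))) +
        outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
      dd[dd < 0] <- 0
      if (!is.null(exclude_self_idx)) {
        dd[cbind(seq_len(nrow(a)), exclude_self_idx)] <- Inf
      }
      sqrt(apply(dd, 1, min))
    }
    u <- nn_dist(probes, x)
    w <- nn_dist(x[samp, , drop = FALSE], x, exclude_self_idx = samp)
    sum(u) / (sum(u) + sum(w))
  })
}

# Ray-casting point-in-polygon test; polygon vertices (hx, hy) in order.
points_in_polygon <- function(p, hx, hy) {
  nv <- length(hx)
  inside <- rep(FALSE, nrow(p))
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- ((hy[i] > p[, 2]) != (hy[j] > p[, 2])) &
      (p[, 1] < (hx[j] - hx[i]) * (p[, 2] - hy[i]) / (hy[j] - hy[i]) + hx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Fraction of freshly sampled triplets satisfied by an embedding
#'
#' Samples one epoch of triplets from a neighbour index built on the
#' original (preprocessed) data and reports the fraction whose embedded
#' anchor-positive distance is strictly smaller than the embedded
#' anchor-negative distance.  A well-trained structure-preserving model
#' satisfies the large majority of fresh triplets it was never shown.
#'
#' @param model A fitted [triplet_embedding()] model.
#' @param data The data the model was fitted on.
#' @param seed Optional seed for the triplet draw.
#' @return Fraction in `[0, 1]`.
#' @export
triplet_satisfaction <- function(model, data, seed = NULL) {
  stopifnot(inherits(model, "triplet_embedding"))
  x <- as_feature_matrix(data, arg = "data")
  xp <- apply_preprocessing(model, x)
  with_seed(seed, {
    index <- build_index(xp, k = model$config$k,
                         n_trees = model$config$n_trees, seed = draw_seed())
    tri <- sample_epoch_triplets(index)
    emb <- as.matrix(predict(model, x))
    dap <- embedding_distance(emb[tri$anchor, , drop = FALSE],
                              emb[tri$positive, , drop = FALSE])
    dan <- embedding_distance(emb[tri$anchor, , drop = FALSE],
                              emb[tri$negative, , drop = FALSE])
    mean(dap < dan)
  })
}
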