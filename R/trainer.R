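# Training: dynamic triplet sampling over the KNN graph, the epoch loop with
# Adam and early stopping, and the fitted model's parametric out-of-sample
# transform.

#' Sample one epoch of training triplets
#'
#' Emits exactly one triplet per observation, anchors in shuffled order.  The
#' positive is drawn uniformly from the anchor's k-nearest-neighbour list;
#' the negative uniformly (by rejection) from the rows outside the anchor's
#' list and distinct from the anchor.  Triplets are resampled every epoch,
#' so successive epochs train on different triplet sets that together mix
#' local (positive) and global (negative) structure.
#'
#' @param index A [build_index()] result.
#' @param seed Optional seed.
#' @return Tibble with integer columns `anchor`, `positive`, `negative`
#'   (1-based row indices), one row per observation.
#' @export
sample_epoch_triplets <- function(index, seed = NULL) {
  stopifnot(inherits(index, "neighbour_index"))
  n <- index$n_obs
  k <- index$k
  if (n <= k + 1) {
    abort(sprintf(
      "Cannot sample negatives: n_obs (%d) must exceed k + 1 (%d).", n, k + 1
    ))
  }
  with_seed(seed, {
    anchors <- sample.int(n)
    positives <- index$idx[cbind(anchors, sample.int(k, n, replace = TRUE))]
    negatives <- sample.int(n, n, replace = TRUE)
    repeat {
      bad <- negatives == anchors |
        rowSums(index$idx[anchors, , drop = FALSE] == negatives) > 0
      if (!any(bad)) break
      negatives[bad] <- sample.int(n, sum(bad), replace = TRUE)
    }
    tibble(anchor = anchors, positive = positives, negative = negatives)
  })
}

#' Fit a structure-preserving triplet embedding
#'
#' Trains a weight-shared siamese network to place each observation closer
#' to its sampled nearest neighbour (positive) than to a random non-
#' neighbour (negative), by the margin, under the chosen triplet loss.  The
#' result is a parametric map: new observations are embedded with
#' [predict.triplet_embedding()] without refitting.
#'
#' The training recipe: an approximate KNN index is built
#' once on the (preprocessed) input; each epoch resamples one triplet per
#' observation; minibatches of `batch_size` triplets are pushed through the
#' shared encoder and optimised with Adam (`learning_rate` 0.001,
#' `beta1` 0.9, `beta2` 0.999); training halts after `epochs` epochs or as
#' soon as the best epoch loss has failed to improve for `patience`
#' consecutive epochs.
#'
#' @param data Numeric matrix or data frame (observations x features).
#' @param dims Embedding dimensionality (default 2).
#' @param k Neighbourhood size for triplet mining; default [default_k()] of
#'   the row count.
#' @param loss Loss kind: `"pn"` (default), `"standard"`, `"softmax_ratio"`,
#'   or `"softmax_ratio_pn"`.
#' @param metric Distance metric inside the loss: `"euclidean"` (default),
#'   `"manhattan"`, or `"chebyshev"`.
#' @param margin Margin `m` of the hinge (default 1; embeddings are stable
#'   over a wide margin band, roughly 0.1-500, with degradation above that).
#' @param batch_size Minibatch size (default 128).
#' @param epochs Maximum number of epochs (default 1000).
#' @param patience Early-stopping patience in epochs (default 50).
#' @param learning_rate,beta1,beta2 Adam hyperparameters.
#' @param layer_sizes Hidden-layer widths (default `c(128, 128, 128)`).
#' @param dropout_rate Alpha-dropout rate (default 0.1).
#' @param n_trees,search_k Annoy index parameters, see [build_index()].
#' @param arcsinh_cofactor If non-NULL, apply [arcsinh_transform()] with this
#'   cofactor before fitting (recorded, and re-applied by `predict`).
#' @param pca_components If non-NULL, project onto this many principal
#'   components before fitting (the training loadings are recorded and
#'   re-used by `predict`).
#' @param seed Optional global seed; every stochastic stage (index build,
#'   weight initialisation, triplet sampling, dropout masks) draws a child
#'   seed from it, so identical seeds reproduce the fit exactly in
#'   single-threaded BLAS mode.
#' @param verbose Print the epoch loss every 50 epochs.
#' @return An object of class `triplet_embedding` with elements `embedding`
#'   (tibble `te1..teD` for the training rows), `network`, `config`,
#'   `preprocessing`, `loss_history`, `best_epoch`, and `n_obs`.
#' @export
#' @examples
#' \donttest{
#' sm <- generate_smiley(500, seed = 1)
#' fit <- triplet_embedding(lift_to_9d(sm), epochs = 50, seed = 1)
#' head(fit$embedding)
#' }
triplet_embedding <- function(data, dims = 2, k = NULL,
                              loss = c("pn", "standard", "softmax_ratio", "softmax_ratio_pn"),
                              metric = c("euclidean", "manhattan", "chebyshev"),
                              margin = 1, batch_size = 128, epochs = 1000,
                              patience = 50, learning_rate = 0.001,
                              beta1 = 0.9, beta2 = 0.999,
                              layer_sizes = c(128, 128, 128),
                              dropout_rate = 0.1, n_trees = 50, search_k = -1,
                              arcsinh_cofactor = NULL, pca_components = NULL,
                              seed = NULL, verbose = FALSE) {
  loss <- match.arg(loss)
  metric <- match.arg(metric)
  dims <- check_count(dims, "dims")
  batch_size <- check_count(batch_size, "batch_size")
  epochs <- check_count(epochs, "epochs")
  patience <- check_count(patience, "patience")
  if (patience >= epochs) {
    abort("`patience` must be smaller than `epochs`.")
  }
  check_positive_number(margin, "margin", strict = FALSE)

  x <- as_feature_matrix(data, arg = "data")
  raw_dim <- ncol(x)

  preprocessing <- list(arcsinh_cofactor = arcsinh_cofactor, pca = NULL)
  if (!is.null(arcsinh_cofactor)) {
    x <- arcsinh_transform(x, arcsinh_cofactor)
  }

  with_seed(seed, {
    if (!is.null(pca_components)) {
      preprocessing$pca <- pca_fit(x, pca_components, seed = draw_seed())
      x <- pca_project(x, preprocessing$pca)
    }
    n <- nrow(x)
    k <- if (is.null(k)) default_k(n) else check_count(k, "k")
    if (n <= k + 1) {
      abort(sprintf("Need n_obs > k + 1 to sample negatives (n = %d, k = %d).", n, k))
    }

    index <- build_index(x, k = k, n_trees = n_trees, seed = draw_seed(),
                         search_k = search_k)
    network <- init_network(ncol(x), layer_sizes = layer_sizes,
                            embedding_dim = dims, dropout_rate = dropout_rate,
                            seed = draw_seed())

    n_layers <- length(network$W)
    state <- list(
      W = network$W, b = network$b,
      m_w = lapply(network$W, function(w) w * 0),
      v_w = lapply(network$W, function(w) w * 0),
      m_b = lapply(network$b, function(v) v * 0),
      v_b = lapply(network$b, function(v) v * 0),
      t = 0L
    )

    loss_history <- numeric(0)
    best_loss <- Inf
    best_epoch <- 0L
    for (epoch in seq_len(epochs)) {
      tri <- sample_epoch_triplets(index)
      tri0 <- cbind(tri$anchor, tri$positive, tri$negative) - 1L
      res <- .run_epoch_cpp(
        state$W, state$b, state$m_w, state$v_w, state$m_b, state$v_b,
        state$t, x, tri0, batch_size, loss, metric, margin,
        learning_rate, beta1, beta2, 1e-8, dropout_rate, draw_seed()
      )
      if (!isTRUE(res$ok) || !is.finite(res$loss)) {
        abort(sprintf(
          "Non-finite loss at epoch %d (margin = %g): exploding gradients; try a smaller margin or learning rate.",
          epoch, margin
        ))
      }
      state$W <- res$weights
      state$b <- res$biases
      state$m_w <- res$m_w; state$v_w <- res$v_w
      state$m_b <- res$m_b; state$v_b <- res$v_b
      state$t <- res$adam_t
      loss_history[epoch] <- res$loss
      if (res$loss < best_loss) {
        best_loss <- res$loss
        best_epoch <- epoch
      }
      if (verbose && epoch %% 50 == 0) {
        message(sprintf("epoch %d: loss %.5f (best %.5f @ %d)",
                        epoch, res$loss, best_loss, best_epoch))
      }
      if (epoch - best_epoch >= patience) break
    }

    network$W <- state$W
    network$b <- state$b

    emb <- encode(network, x, training = FALSE)
    colnames(emb) <- paste0("te", seq_len(dims))

    structure(
      list(
        embedding = as_tibble(emb),
        network = network,
        config = list(
          dims = dims, k = k, loss = loss, metric = metric, margin = margin,
          batch_size = batch_size, epochs = epochs, patience = patience,
          learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
          layer_sizes = layer_sizes, dropout_rate = dropout_rate,
          n_trees = n_trees, search_k = search_k, seed = seed
        ),
        preprocessing = preprocessing,
        input_dim = raw_dim,
        n_obs = n,
        loss_history = loss_history,
        best_epoch = best_epoch,
        best_loss = best_loss
      ),
      class = "triplet_embedding"
    )
  })
}

apply_preprocessing <- function(model, x) {
  if (!is.null(model$preprocessing$arcsinh_cofactor)) {
    x <- arcsinh_transform(x, model$preprocessing$arcsinh_cofactor)
  }
  if (!is.null(model$preprocessing$pca)) {
    x <- pca_project(x, model$preprocessing$pca)
  }
  x
}

#' Embed new observations through a fitted model
#'
#' Applies the preprocessing recorded at fit time (arcsinh and/or the
#' training PCA loadings) and runs a deterministic inference-mode pass
#' through the encoder.  Embedding a training row reproduces its fit-time
#' coordinates exactly.
#'
#' @param object A fitted [triplet_embedding()] model.
#' @param newdata Numeric matrix or data frame with the same feature count
#'   the model was fitted on.
#' @param ... Unused.
#' @return Tibble of embedding coordinates `te1..teD`, one row per row of
#'   `newdata`.
#' @export
predict.triplet_embedding <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata, arg = "newdata")
  if (ncol(x) != object$input_dim) {
    abort(sprintf(
      "`newdata` has %d columns but the model was fitted on %d.",
      ncol(x), object$input_dim
    ))
  }
  x <- apply_preprocessing(object, x)
  emb <- encode(object$network, x, training = FALSE)
  colnames(emb) <- paste0("te", seq_len(ncol(emb)))
  as_tibble(emb)
}

#' @rdname triplet_embedding
#' @param x A fitted model (print method).
#' @param ... Unused.
#' @method print triplet_embedding
#' @export
print.triplet_embedding <- function(x, ...) {
  cat(sprintf(
    "<triplet_embedding> %d observations -> %d dims | loss %s/%s, margin %g, k %d\n",
    x$n_obs, x$config$dims, x$config$loss, x$config$metric, x$config$margin,
    x$config$k
  ))
  cat(sprintf(
    "  trained %d epochs (best loss %.5f at epoch %d)\n",
    length(x$loss_history), x$best_loss, x$best_epoch
  ))
  invisible(x)
}

MODEL_FORMAT_VERSION <- "tripletembed-model-1"

#' Save / load a fitted embedding model
#'
#' Serialises the full model (weights, architecture, preprocessing
#' provenance and training configuration) to a single file with a format
#' version string; loading a file written by an incompatible version fails
#' with an explicit error.  The round trip is exact: the loaded model embeds
#' any input identically to the original.
#'
#' @param model A fitted [triplet_embedding()] model.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "triplet_embedding"))
  payload <- list(format = MODEL_FORMAT_VERSION, model = model)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e) {
    abort(sprintf("Cannot read model file '%s': %s", path, conditionMessage(e)))
  })
  if (!is.list(payload) || is.null(payload$format)) {
    abort(sprintf("'%s' is not a tripletembed model file.", path))
  }
  if (!identical(payload$format, MODEL_FORMAT_VERSION)) {
    abort(sprintf(
      "Model format mismatch: file has '%s', this package reads '%s'.",
      payload$format, MODEL_FORMAT_VERSION
    ))
  }
  payload$model
}
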