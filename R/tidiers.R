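# broom-style accessors and ggplot2 autoplot methods.

#' Tidy the training history of a fitted embedding
#'
#' @param x A [triplet_embedding()] model.
#' @param ... Unused.
#' @return Tibble with columns `epoch` and `loss`.
#' @export
tidy.triplet_embedding <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' One-row summary of a fitted embedding
#'
#' @inheritParams tidy.triplet_embedding
#' @return One-row tibble: data size, architecture and training endpoints.
#' @export
glance.triplet_embedding <- function(x, ...) {
  tibble(
    n_obs = x$n_obs,
    input_dim = x$input_dim,
    dims = x$config$dims,
    k = x$config$k,
    loss = x$config$loss,
    metric = x$config$metric,
    margin = x$config$margin,
    epochs_run = length(x$loss_history),
    best_epoch = x$best_epoch,
    best_loss = x$best_loss,
    final_loss = x$loss_history[length(x$loss_history)]
  )
}

#' Attach embedding coordinates to the training data
#'
#' @inheritParams tidy.triplet_embedding
#' @param data Optional data frame of the training rows to bind the
#'   coordinates to; defaults to the coordinates alone.
#' @return Tibble of `data` (if given) with embedding columns `te1..teD`
#'   appended.
#' @export
augment.triplet_embedding <- function(x, data = NULL, ...) {
  if (is.null(data)) {
    return(x$embedding)
  }
  data <- as_tibble(data)
  if (nrow(data) != nrow(x$embedding)) {
    abort("`data` must have one row per training observation.")
  }
  dplyr::bind_cols(data, x$embedding)
}

#' Scatter plot of a fitted embedding
#'
#' @param object A [triplet_embedding()] model.
#' @param labels Optional vector colouring the points (e.g. cluster labels).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.triplet_embedding <- function(object, labels = NULL, ...) {
  df <- object$embedding
  p <- if (is.null(labels)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$te1, y = .data$te2))
  } else {
    df$label <- factor(labels)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$te1, y = .data$te2,
                                     colour = .data$label))
  }
  p +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2") +
    ggplot2::theme_minimal()
}

#' Boxplot of structure-preservation correlations per method
#'
#' @param object A [structure_benchmark()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.structure_report <- function(object, ...) {
  ggplot2::ggplot(object$per_subsample,
                  ggplot2::aes(x = .data$method, y = .data$pcc)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Mantel correlation (centroid distances)") +
    ggplot2::theme_minimal()
}
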