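# The encoder: a dense feed-forward network of three SELU layers with alpha
# dropout, topped by a linear embedding head.  All three branches of the
# siamese arrangement share this single set of weights — there is only one
# network object, applied to anchors, positives and negatives alike.

# Self-normalising activation constants.
SELU_ALPHA <- 1.6733
SELU_LAMBDA <- 1.0507

#' Scaled exponential linear unit
#'
#' `lambda * x` for `x > 0` and `lambda * alpha * (exp(x) - 1)` for
#' `x <= 0`, applied elementwise.  With the canonical constants
#' (`alpha = 1.6733`, `lambda = 1.0507`) a deep stack of these activations is
#' self-normalising: activation means and variances stay near 0 and 1
#' through depth, removing the need for batch normalisation.
#'
#' @param x Numeric vector, matrix or array.
#' @param alpha,lambda Activation constants.
#' @return Object of the same shape as `x`.
#' @export
#' @examples
#' selu(c(-1, 0, 1))
selu <- function(x, alpha = SELU_ALPHA, lambda = SELU_LAMBDA) {
  ifelse(x > 0, lambda * x, lambda * alpha * (exp(x) - 1))
}

selu_deriv <- function(x, alpha = SELU_ALPHA, lambda = SELU_LAMBDA) {
  ifelse(x > 0, lambda, lambda * alpha * exp(x))
}

#' Alpha dropout
#'
#' Dropout matched to the SELU activation: instead of zeroing units, dropped
#' units are set to the SELU saturation value `-lambda * alpha`, and an
#' affine correction (scale and shift) restores the pre-drop mean and
#' variance in expectation, preserving the self-normalising property.  In
#' inference mode (`training = FALSE`) or at `rate = 0` the function is the
#' identity.
#'
#' @param x Numeric matrix of activations.
#' @param rate Drop probability in `[0, 1)`.
#' @param training Logical; apply dropout (TRUE) or pass through (FALSE).
#' @param seed Optional seed for the drop mask.
#' @param alpha,lambda SELU constants the correction is matched to.
#' @return Matrix of the same shape as `x`.
#' @export
alpha_dropout <- function(x, rate = 0.1, training = TRUE, seed = NULL,
                          alpha = SELU_ALPHA, lambda = SELU_LAMBDA) {
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate >= 1) {
    abort("`rate` must be a single number in [0, 1).")
  }
  if (!training || rate == 0) {
    return(x)
  }
  ap <- -lambda * alpha                       # SELU saturation value
  q <- 1 - rate
  scale <- (q + ap^2 * q * rate)^(-1 / 2)     # restores unit variance
  shift <- -scale * ap * rate                 # restores zero mean
  with_seed(seed, {
    keep <- matrix(stats::runif(length(x)) >= rate, nrow(x), ncol(x))
    scale * (ifelse(keep, x, ap)) + shift
  })
}

#' Initialise the encoder network
#'
#' Three dense hidden layers (128 units each by default) with SELU
#' activations, followed by a linear embedding head of `embedding_dim`
#' units.  Hidden weights are drawn from the LeCun normal distribution
#' (sd = `1/sqrt(fan_in)`, the initialisation the self-normalising property
#' requires); the head uses Glorot uniform
#' (`+/- sqrt(6 / (fan_in + fan_out))`).  Biases start at zero.
#'
#' @param input_dim Number of input features.
#' @param layer_sizes Integer vector of hidden-layer widths
#'   (default `c(128, 128, 128)`).
#' @param embedding_dim Output dimensionality (default 2).
#' @param dropout_rate Alpha-dropout rate applied after each hidden layer
#'   during training (default 0.1).
#' @param seed Optional seed; identical seeds give identical weights.
#' @return An object of class `selu_network`: weights `W` (list of
#'   matrices), biases `b` (list of vectors), and the architecture fields.
#' @export
init_network <- function(input_dim, layer_sizes = c(128, 128, 128),
                         embedding_dim = 2, dropout_rate = 0.1, seed = NULL) {
  input_dim <- check_count(input_dim, "input_dim")
  embedding_dim <- check_count(embedding_dim, "embedding_dim")
  layer_sizes <- vapply(layer_sizes, check_count, integer(1), name = "layer_sizes")
  dims <- c(input_dim, layer_sizes, embedding_dim)
  n_layers <- length(dims) - 1L
  with_seed(seed, {
    W <- vector("list", n_layers)
    b <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      fan_in <- dims[l]
      fan_out <- dims[l + 1]
      if (l < n_layers) {
        W[[l]] <- matrix(stats::rnorm(fan_in * fan_out, 0, 1 / sqrt(fan_in)),
                         fan_in, fan_out)
      } else {
        lim <- sqrt(6 / (fan_in + fan_out))
        W[[l]] <- matrix(stats::runif(fan_in * fan_out, -lim, lim),
                         fan_in, fan_out)
      }
      b[[l]] <- numeric(fan_out)
    }
    structure(
      list(W = W, b = b, input_dim = input_dim, layer_sizes = layer_sizes,
           embedding_dim = embedding_dim, dropout_rate = dropout_rate,
           alpha = SELU_ALPHA, lambda = SELU_LAMBDA),
      class = "selu_network"
    )
  })
}

#' Run observations through the encoder
#'
#' Dense -> SELU -> alpha dropout, repeated for each hidden layer, then the
#' linear head.  With `training = FALSE` (the default) dropout is the
#' identity and the output is a deterministic function of the weights and
#' the input.
#'
#' @param network A `selu_network`.
#' @param x Numeric matrix whose column count equals the network's
#'   `input_dim`.
#' @param training Logical; apply dropout masks (TRUE) or run in inference
#'   mode (FALSE, default).
#' @param seed Optional seed for the dropout masks when `training = TRUE`.
#' @return Numeric matrix `nrow(x)` x `embedding_dim`.
#' @export
encode <- function(network, x, training = FALSE, seed = NULL) {
  stopifnot(inherits(network, "selu_network"))
  x <- as_feature_matrix(x, arg = "x")
  if (ncol(x) != network$input_dim) {
    abort(sprintf(
      "`x` has %d columns but the network expects %d.",
      ncol(x), network$input_dim
    ))
  }
  n_layers <- length(network$W)
  a <- x
  with_seed(seed, {
    for (l in seq_len(n_layers - 1L)) {
      z <- a %*% network$W[[l]]
      z <- sweep(z, 2, network$b[[l]], "+")
      a <- selu(z, network$alpha, network$lambda)
      if (training && network$dropout_rate > 0) {
        a <- alpha_dropout(a, network$dropout_rate, training = TRUE,
                           alpha = network$alpha, lambda = network$lambda)
      }
    }
    z <- a %*% network$W[[n_layers]]
    sweep(z, 2, network$b[[n_layers]], "+")
  })
}
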