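# Synthetic benchmark generators.
#
# Three two-dimensional datasets exercise qualitatively different structure:
# pure uniform noise (an embedding should NOT invent clusters from it), the
# Cassini problem (three convex-ish clusters with meaningful inter-cluster
# geometry), and the Smiley (four parts of varying shape and scale).  Each is
# generated in 2-D and can be lifted to nine dimensions with a fixed
# polynomial map, giving a high-dimensional input whose ground-truth planar
# structure is known exactly.
#
# Shape constants follow the classic mlbench-style conventions for these
# datasets; they live in one block so the figures can be tuned in a single
# place.  Downstream checks depend only on topology (number of parts,
# relative centroid positions), not on the exact constants.

smiley_shape <- list(
  eye_centres = list(c(-0.8, 1.0), c(0.8, 1.0)),
  eye_sd = 0.15,
  nose_y = c(-0.3, 0.6),          # trapezoid vertical extent
  nose_half_width = c(0.1, 0.3),  # half-width at top and bottom edges
  mouth_x = c(-1, 1),
  mouth_curvature = 0.4,          # y = curvature * x^2 + offset
  mouth_offset = -1,
  mouth_sd = 0.05,                # vertical Gaussian jitter
  proportions = c(eye_left = 1 / 6, eye_right = 1 / 6, nose = 1 / 4,
                  mouth = 5 / 12)
)

cassini_shape <- list(
  band_radius = c(0.75, 1.25),  # inner/outer radius of each banana annulus
  band_shift = 0.35,            # vertical offset of the banana centres
  disc_radius = 0.3
)

# Split n into parts proportional to `p`, differing from exact proportions
# only by rounding (largest-remainder method).
proportional_sizes <- function(n, p) {
  p <- p / sum(p)
  raw <- n * p
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    top <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[top] <- sizes[top] + 1
  }
  as.integer(sizes)
}

new_synthetic <- function(x, y, label) {
  tibble(x = x, y = y, label = factor(label))
}

#' Uniform-noise benchmark dataset
#'
#' `n` points i.i.d. uniform on the unit square, all in one class.  A
#' structure-preserving embedding of (a lift of) this data should remain
#' unclustered; methods that fabricate compact clusters from noise fail this
#' benchmark.
#'
#' @param n Number of points (default 5000).
#' @param seed Optional seed; identical inputs give identical output.
#' @return Tibble with columns `x`, `y`, `label`.
#' @export
generate_uniform <- function(n = 5000, seed = NULL) {
  n <- check_count(n, "n")
  with_seed(seed, new_synthetic(stats::runif(n), stats::runif(n), rep("noise", n)))
}

#' Cassini benchmark dataset
#'
#' Three labelled components: two banana-shaped bands (half-annuli opening
#' towards the centre) above and below a central disc, points uniform within
#' each region, sizes as balanced as `n` allows.
#'
#' @inheritParams generate_uniform
#' @return Tibble with columns `x`, `y`, `label` (levels `"1"`, `"2"`, `"3"`;
#'   `"2"` is the central disc).
#' @export
generate_cassini <- function(n = 5000, seed = NULL) {
  n <- check_count(n, "n")
  if (n < 3) abort("`n` must be at least 3 (one point per cluster).")
  s <- cassini_shape
  with_seed(seed, {
    sizes <- proportional_sizes(n, c(1, 1, 1))
    band <- function(m, upper) {
      # Uniform over a half-annulus: area-correct radius sampling.
      r <- sqrt(stats::runif(m, s$band_radius[1]^2, s$band_radius[2]^2))
      theta <- stats::runif(m, 0, pi)
      if (upper) {
        cbind(r * cos(theta), r * sin(theta) + s$band_shift)
      } else {
        cbind(r * cos(theta), -r * sin(theta) - s$band_shift)
      }
    }
    disc <- function(m) {
      r <- s$disc_radius * sqrt(stats::runif(m))
      theta <- stats::runif(m, 0, 2 * pi)
      cbind(r * cos(theta), r * sin(theta))
    }
    pts <- rbind(band(sizes[1], TRUE), disc(sizes[2]), band(sizes[3], FALSE))
    new_synthetic(pts[, 1], pts[, 2], rep(c("1", "2", "3"), sizes))
  })
}

#' Smiley benchmark dataset
#'
#' Four labelled parts: two isotropic Gaussian eyes, a trapezoid nose
#' (uniform), and a parabola mouth with vertical Gaussian noise.  Part
#' proportions are fixed (1/6 per eye, 1/4 nose, 5/12 mouth).
#'
#' @inheritParams generate_uniform
#' @return Tibble with columns `x`, `y`, `label` (levels `"eye_left"`,
#'   `"eye_right"`, `"nose"`, `"mouth"`).
#' @export
generate_smiley <- function(n = 5000, seed = NULL) {
  n <- check_count(n, "n")
  if (n < 4) abort("`n` must be at least 4 (one point per part).")
  s <- smiley_shape
  with_seed(seed, {
    sizes <- proportional_sizes(n, s$proportions)
    eye <- function(m, centre) {
      cbind(stats::rnorm(m, centre[1], s$eye_sd), stats::rnorm(m, centre[2], s$eye_sd))
    }
    nose <- function(m) {
      y <- stats::runif(m, s$nose_y[1], s$nose_y[2])
      # half-width interpolates linearly from the top edge down
      frac <- (s$nose_y[2] - y) / diff(s$nose_y)
      w <- s$nose_half_width[1] + frac * diff(s$nose_half_width)
      cbind(stats::runif(m, -w, w), y)
    }
    mouth <- function(m) {
      x <- stats::runif(m, s$mouth_x[1], s$mouth_x[2])
      y <- s$mouth_curvature * x^2 + s$mouth_offset + stats::rnorm(m, 0, s$mouth_sd)
      cbind(x, y)
    }
    pts <- rbind(eye(sizes[1], s$eye_centres[[1]]),
                 eye(sizes[2], s$eye_centres[[2]]),
                 nose(sizes[3]),
                 mouth(sizes[4]))
    new_synthetic(pts[, 1], pts[, 2],
                  rep(c("eye_left", "eye_right", "nose", "mouth"), sizes))
  })
}

#' Lift planar coordinates into nine polynomial dimensions
#'
#' Maps each 2-D point (x, y) to the monomial vector
#' (x + y, x - y, xy, x^2, y^2, x^2 y, x y^2, x^3, y^3), in exactly that
#' column order.  The lift is deterministic and injective on generic point
#' sets, so the planar structure is recoverable in principle from the 9-D
#' image — which is what makes these datasets a ground-truth benchmark for
#' structure-preserving embeddings.
#'
#' @param xy A two-column numeric matrix, or a data frame containing numeric
#'   columns `x` and `y` (extra columns such as `label` are ignored).
#' @return Tibble with nine numeric columns `x_plus_y`, `x_minus_y`, `xy`,
#'   `x2`, `y2`, `x2y`, `xy2`, `x3`, `y3`.
#' @export
#' @examples
#' lift_to_9d(cbind(1, 2))  # (3, -1, 2, 1, 4, 2, 4, 1, 8)
lift_to_9d <- function(xy) {
  if (is.data.frame(xy) && all(c("x", "y") %in% names(xy))) {
    xy <- cbind(xy$x, xy$y)
  }
  xy <- as_feature_matrix(xy, arg = "xy")
  if (ncol(xy) != 2) {
    abort(sprintf("`xy` must have exactly 2 columns, got %d.", ncol(xy)))
  }
  x <- xy[, 1]
  y <- xy[, 2]
  tibble(
    x_plus_y = x + y,
    x_minus_y = x - y,
    xy = x * y,
    x2 = x^2,
    y2 = y^2,
    x2y = x^2 * y,
    xy2 = x * y^2,
    x3 = x^3,
    y3 = y^3
  )
}

#' Isotropic Gaussian blob mixture
#'
#' Balanced mixture of `centers` spherical Gaussians with centres drawn
#' uniformly in `[-10, 10]^d`.  Used for nearest-neighbour recall checks and
#' for the fixed-dimension scaling experiments (32-dimensional inputs of
#' doubling size).
#'
#' @param n Number of points.
#' @param d Dimensionality (default 32).
#' @param centers Number of mixture components (default 5).
#' @param sd Within-component standard deviation (default 1).
#' @param seed Optional seed.
#' @return List with `data` (tibble of `d` feature columns `V1..Vd`) and
#'   `label` (factor of component memberships).
#' @export
generate_blobs <- function(n = 5000, d = 32, centers = 5, sd = 1, seed = NULL) {
  n <- check_count(n, "n")
  d <- check_count(d, "d")
  centers <- check_count(centers, "centers")
  with_seed(seed, {
    mu <- matrix(stats::runif(centers * d, -10, 10), centers, d)
    sizes <- proportional_sizes(n, rep(1, centers))
    lab <- rep(seq_len(centers), sizes)
    pts <- mu[lab, , drop = FALSE] + matrix(stats::rnorm(n * d, 0, sd), n, d)
    colnames(pts) <- paste0("V", seq_len(d))
    list(data = as_tibble(pts), label = factor(lab))
  })
}
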