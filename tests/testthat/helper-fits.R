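# Shared fitted models for the heavier end-to-end tests.  The Smiley-9D
# benchmark (n = 5000) at default training settings is used by several
# structure-preservation checks; models are fitted lazily, once per seed,
# and cached for the duration of the test run.

.fit_cache <- new.env(parent = emptyenv())

smiley_benchmark <- function() {
  if (is.null(.fit_cache$smiley)) {
    sm <- generate_smiley(5000, seed = 101)
    .fit_cache$smiley <- list(
      points = sm,
      coords2d = cbind(sm$x, sm$y),
      lifted = as.matrix(lift_to_9d(sm))
    )
  }
  .fit_cache$smiley
}

smiley_fit <- function(seed) {
  key <- paste0("fit_", seed)
  if (is.null(.fit_cache[[key]])) {
    .fit_cache[[key]] <- triplet_embedding(smiley_benchmark()$lifted, seed = seed)
  }
  .fit_cache[[key]]
}
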