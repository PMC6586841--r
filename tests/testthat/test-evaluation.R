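test_that("centroid distances match hand arithmetic in sorted label order", {
  x <- matrix(c(0, 2, 10, 12, 20, 22), ncol = 1)
  lab <- rep(c("a", "b", "c"), each = 2)
  d <- centroid_distances(x, lab)
  expect_equal(rownames(d), c("a", "b", "c"))
  expect_equal(d["a", "b"], 10)
  expect_equal(d["b", "c"], 10)
  expect_equal(d["a", "c"], 20)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d, t(d))

  # permuting row order leaves the matrix unchanged (sorted-label convention)
  ord <- c(5, 3, 1, 6, 4, 2)
  expect_equal(centroid_distances(x[ord, , drop = FALSE], lab[ord]), d)

  # degenerate: all clusters on one point
  z <- matrix(1, 6, 2)
  expect_equal(unname(centroid_distances(z, lab)), matrix(0, 3, 3))

  expect_error(centroid_distances(x, rep(c("a", "b"), 3)), "3 distinct")
})

test_that("mantel correlation is exact under identity and affine maps", {
  set.seed(40)
  pts <- matrix(rnorm(12), 6, 2)
  d1 <- as.matrix(dist(pts))
  dimnames(d1) <- list(letters[1:6], letters[1:6])
  expect_equal(mantel_test(d1, d1, n_perm = 99, seed = 1)$pcc, 1)
  expect_equal(mantel_test(d1, 3 * d1 + 2, n_perm = 99, seed = 1)$pcc, 1)

  # invariant to a simultaneous relabeling of both matrices
  m2 <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  dimnames(m2) <- dimnames(d1)
  p <- c(4, 2, 6, 1, 3, 5)
  r1 <- mantel_test(d1, m2, n_perm = 9, seed = 1)$pcc
  r2 <- mantel_test(d1[p, p], m2[p, p], n_perm = 9, seed = 1)$pcc
  expect_equal(r1, r2)

  expect_error(mantel_test(d1[1:2, 1:2], d1[1:2, 1:2]), "at least 3")
  z <- matrix(0, 4, 4)
  expect_error(mantel_test(z, z), "Zero variance")
  bad <- d1
  rownames(bad) <- colnames(bad) <- LETTERS[1:6]
  expect_error(mantel_test(d1, bad), "different cluster sets")
})

test_that("permutation p-values agree with the exhaustive oracle", {
  set.seed(41)
  for (rep in 1:3) {
    a <- matrix(rnorm(12), 6, 2)
    b <- matrix(rnorm(12), 6, 2)
    d1 <- as.matrix(dist(a))
    d2 <- as.matrix(dist(b))
    v1 <- d1[upper.tri(d1)]
    r_obs <- cor(v1, d2[upper.tri(d2)])
    perms <- all_permutations(6L)
    r_all <- vapply(perms, function(p) {
      dp <- d2[p, p]
      cor(v1, dp[upper.tri(dp)])
    }, numeric(1))
    p_oracle <- mean(abs(r_all) >= abs(r_obs))
    got <- mantel_test(d1, d2, n_perm = 999, seed = rep)
    expect_lt(abs(got$p_value - p_oracle), 0.1)
    expect_gt(got$p_value, 0)
    expect_lte(got$p_value, 1)
  }
})

test_that("the mantel statistic matches vegan's", {
  skip_if_not_installed("vegan")
  set.seed(42)
  d1 <- as.matrix(dist(matrix(rnorm(14), 7, 2)))
  d2 <- as.matrix(dist(matrix(rnorm(14), 7, 2)))
  ours <- mantel_test(d1, d2, n_perm = 9, seed = 1)$pcc
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 9)$statistic
  expect_equal(ours, unname(ref), tolerance = 1e-12)
})

test_that("an isometric embedder scores perfect structure preservation", {
  b <- generate_blobs(600, d = 2, centers = 4, seed = 43)
  x <- as.matrix(b$data)
  th <- 0.6
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rep <- structure_benchmark(
    x, b$label,
    embedders = list(rigid = function(m) m %*% rot + 5),
    n_subsamples = 5, subsample_size = 200, seed = 44
  )
  expect_true(all(abs(rep$per_subsample$pcc - 1) < 1e-12))
  expect_equal(rep$summary$median_pcc, 1)

  # constant map exercises the zero-variance error path
  expect_error(
    structure_benchmark(
      x, b$label, embedders = list(flat = function(m) matrix(1, nrow(m), 2)),
      n_subsamples = 1, subsample_size = 200, seed = 45
    ),
    "Zero variance"
  )
})

test_that("subsampling is without replacement and seed-reproducible", {
  b <- generate_blobs(400, d = 2, centers = 3, seed = 46)
  x <- as.matrix(b$data)
  ident <- list(id = function(m) m)
  r1 <- structure_benchmark(x, b$label, ident, n_subsamples = 4,
                            subsample_size = 100, seed = 47)
  r2 <- structure_benchmark(x, b$label, ident, n_subsamples = 4,
                            subsample_size = 100, seed = 47)
  expect_identical(r1$per_subsample, r2$per_subsample)
})

test_that("two methods are compared with a two-tailed t-test", {
  b <- generate_blobs(400, d = 4, centers = 4, seed = 48)
  x <- as.matrix(b$data)
  set.seed(49)
  rep <- structure_benchmark(
    x, b$label,
    embedders = list(
      pca = function(m) pca_reduce(m, 2),
      noise = function(m) matrix(rnorm(2 * nrow(m)), ncol = 2)
    ),
    n_subsamples = 6, subsample_size = 150, seed = 50
  )
  expect_equal(nrow(rep$comparison), 1)
  expect_true(rep$summary$median_pcc[rep$summary$method == "pca"] >
              rep$summary$median_pcc[rep$summary$method == "noise"])
  expect_true(is.finite(rep$comparison$t_statistic))
})

test_that("extrapolation is perfect on separable blobs and at chance on shuffled labels", {
  b <- generate_blobs(800, d = 5, centers = 3, sd = 0.3, seed = 51)
  x <- as.matrix(b$data)
  acc <- extrapolation_experiment(x, b$label, subset_sizes = 80, repeats = 2,
                                  seed = 52, epochs = 40, patience = 39)
  expect_gte(min(acc$accuracy), 0.98)
  expect_equal(dim(acc$confusion[[1]]), c(3, 3))

  set.seed(53)
  shuffled <- sample(b$label)
  acc0 <- extrapolation_experiment(x, shuffled, subset_sizes = 80, repeats = 2,
                                   seed = 54, epochs = 40, patience = 39)
  expect_true(all(acc0$accuracy > 0.2 & acc0$accuracy < 0.5))

  expect_error(
    extrapolation_experiment(x, b$label, subset_sizes = 800, seed = 1),
    "smaller"
  )
})

test_that("identical seeds give identical structure; fresh noise gives none", {
  sm <- generate_smiley(300, seed = 55)
  x <- as.matrix(lift_to_9d(sm))
  f1 <- triplet_embedding(x, epochs = 30, patience = 29, seed = 56)
  f2 <- triplet_embedding(x, epochs = 30, patience = 29, seed = 56)
  d1 <- centroid_distances(as.matrix(f1$embedding), sm$label)
  d2 <- centroid_distances(as.matrix(f2$embedding), sm$label)
  expect_equal(mantel_test(d1, d2, n_perm = 9, seed = 1)$pcc, 1)

  # null behaviour: random embeddings agree with each other only by chance
  set.seed(57)
  null_pcc <- replicate(40, {
    e1 <- matrix(rnorm(600), 300, 2)
    e2 <- matrix(rnorm(600), 300, 2)
    c1 <- centroid_distances(e1, sm$label)
    c2 <- centroid_distances(e2, sm$label)
    cor(c1[upper.tri(c1)], c2[upper.tri(c2)])
  })
  expect_lt(abs(mean(null_pcc)), 0.25)
})

test_that("hopkins statistic separates random from clustered data", {
  u <- generate_uniform(2000, seed = 58)
  h_u <- hopkins_statistic(cbind(u$x, u$y), seed = 59)
  expect_lt(abs(h_u - 0.5), 0.07)

  b <- generate_blobs(2000, d = 2, centers = 4, sd = 0.3, seed = 60)
  h_b <- hopkins_statistic(as.matrix(b$data), seed = 61)
  expect_gt(h_b, 0.8)

  # isometry robustness: rotating the uniform square changes nothing material
  th <- pi / 4
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  h_rot <- hopkins_statistic(cbind(u$x, u$y) %*% rot, seed = 59)
  expect_lt(abs(h_rot - h_u), 0.06)
})
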