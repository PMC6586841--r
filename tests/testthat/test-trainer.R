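test_that("epoch triplets satisfy the membership invariants", {
  x <- matrix(c(0, 0.1, 0.2, 5), ncol = 1)
  idx <- build_index(x, k = 1, seed = 1)
  tri <- sample_epoch_triplets(idx, seed = 2)
  expect_setequal(tri$anchor, 1:4)  # exactly one triplet per anchor
  for (r in seq_len(4)) {
    a <- tri$anchor[r]
    expect_true(tri$positive[r] %in% idx$idx[a, ])
    expect_false(tri$negative[r] %in% c(a, idx$idx[a, ]))
    expect_length(unique(c(a, tri$positive[r], tri$negative[r])), 3)
  }

  b <- generate_blobs(200, d = 4, seed = 3)
  idx2 <- build_index(as.matrix(b$data), k = 10, seed = 4)
  tri2 <- sample_epoch_triplets(idx2, seed = 5)
  in_knn <- tri2$positive == idx2$idx[cbind(tri2$anchor, 1)]
  for (j in 2:10) in_knn <- in_knn | tri2$positive == idx2$idx[cbind(tri2$anchor, j)]
  expect_true(all(in_knn))
  neg_in_knn <- rowSums(idx2$idx[tri2$anchor, ] == tri2$negative) > 0
  expect_false(any(neg_in_knn | tri2$negative == tri2$anchor))
})

test_that("triplets are resampled every epoch from one stream", {
  b <- generate_blobs(1000, d = 4, seed = 6)
  idx <- build_index(as.matrix(b$data), k = 10, seed = 7)
  set.seed(8)
  t1 <- sample_epoch_triplets(idx)
  t2 <- sample_epoch_triplets(idx)
  expect_false(identical(t1, t2))
})

test_that("positive selection is uniform over the neighbour list", {
  b <- generate_blobs(1000, d = 4, seed = 9)
  idx <- build_index(as.matrix(b$data), k = 4, seed = 10)
  set.seed(11)
  rank_counts <- numeric(4)
  for (e in 1:100) {
    tri <- sample_epoch_triplets(idx)
    pos_rank <- mapply(function(a, p) match(p, idx$idx[a, ]),
                       tri$anchor, tri$positive)
    rank_counts <- rank_counts + tabulate(pos_rank, 4)
  }
  freq <- rank_counts / sum(rank_counts)
  expect_true(all(abs(freq - 0.25) < 0.01))
})

test_that("sampling refuses when no negatives exist", {
  x <- matrix(rnorm(8), 4, 2)
  idx <- build_index(x, k = 3, seed = 1)
  expect_error(sample_epoch_triplets(idx), "exceed")
})

test_that("training reduces the loss and is seed-reproducible", {
  sm <- generate_smiley(500, seed = 20)
  x <- as.matrix(lift_to_9d(sm))
  f1 <- triplet_embedding(x, epochs = 60, patience = 59, seed = 21)
  expect_lt(tail(f1$loss_history, 1), f1$loss_history[1])
  f2 <- triplet_embedding(x, epochs = 60, patience = 59, seed = 21)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$embedding, f2$embedding)
})

test_that("early stopping length is bounded by best epoch plus patience", {
  sm <- generate_smiley(400, seed = 22)
  x <- as.matrix(lift_to_9d(sm))
  fit <- triplet_embedding(x, epochs = 300, patience = 20, seed = 23)
  expect_equal(fit$best_loss, min(fit$loss_history))
  expect_equal(fit$best_epoch, which.min(fit$loss_history))
  expect_lte(length(fit$loss_history), fit$best_epoch + 20 + 1)
})

test_that("a far point is embedded away from a tight cluster", {
  x <- matrix(c(0, 0, 0.01, 0, 0, 0.01, 10, 10), 4, 2, byrow = TRUE)
  fit <- triplet_embedding(x, k = 1, epochs = 300, patience = 299,
                           batch_size = 4, seed = 24)
  e <- as.matrix(fit$embedding)
  near <- embedding_distance(e[1, ], e[2, ])
  far <- embedding_distance(e[1, ], e[4, ])
  expect_lt(near, far)
})

test_that("the transform is deterministic and a pure function of rows", {
  sm <- generate_smiley(300, seed = 25)
  x <- as.matrix(lift_to_9d(sm))
  fit <- triplet_embedding(x, epochs = 30, patience = 29, seed = 26)
  p1 <- predict(fit, x)
  p2 <- predict(fit, x)
  expect_identical(p1, p2)
  # training rows reproduce their fit-time embedding
  expect_equal(as.matrix(p1), as.matrix(fit$embedding), ignore_attr = TRUE)
  # duplicated held-out point gets identical coordinates
  new <- x[c(7, 7), , drop = FALSE] + 0.05
  pn <- as.matrix(predict(fit, new))
  expect_identical(pn[1, ], pn[2, ])
  expect_error(predict(fit, x[, 1:5]), "columns")
})

test_that("preprocessing recorded at fit time is replayed by predict", {
  b <- generate_blobs(300, d = 12, centers = 3, seed = 27)
  x <- abs(as.matrix(b$data))
  fit <- triplet_embedding(x, epochs = 30, patience = 29, seed = 28,
                           arcsinh_cofactor = 5, pca_components = 6)
  expect_equal(fit$preprocessing$arcsinh_cofactor, 5)
  expect_equal(ncol(fit$preprocessing$pca$rotation), 6)
  # predict on training data reproduces fit-time embedding (same pipeline)
  expect_equal(as.matrix(predict(fit, x)), as.matrix(fit$embedding),
               ignore_attr = TRUE)
})

test_that("model files round-trip exactly and fail loudly when corrupt", {
  sm <- generate_smiley(200, seed = 29)
  x <- as.matrix(lift_to_9d(sm))
  fit <- triplet_embedding(x, epochs = 20, patience = 19, seed = 30,
                           loss = "pn", metric = "manhattan")
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, f)
  back <- load_model(f)
  expect_identical(predict(back, x), predict(fit, x))
  expect_equal(back$config$metric, "manhattan")
  expect_equal(back$config$loss, "pn")

  # truncated file
  raw <- readBin(f, "raw", file.size(f))
  f2 <- withr::local_tempfile(fileext = ".rds")
  writeBin(raw[1:20], f2)
  expect_error(load_model(f2), "Cannot read")

  # version mismatch
  f3 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "tripletembed-model-0", model = NULL), f3)
  expect_error(load_model(f3), "format mismatch")
})

test_that("tidy, glance, augment and autoplot expose the fit", {
  sm <- generate_smiley(200, seed = 31)
  x <- lift_to_9d(sm)
  fit <- triplet_embedding(x, epochs = 15, patience = 14, seed = 32)
  td <- tidy(fit)
  expect_named(td, c("epoch", "loss"))
  expect_equal(nrow(td), length(fit$loss_history))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 200)
  expect_equal(gl$dims, 2)
  expect_equal(gl$best_loss, min(fit$loss_history))
  au <- augment(fit, sm)
  expect_named(au, c("x", "y", "label", "te1", "te2"))
  p <- autoplot(fit, labels = sm$label)
  expect_s3_class(p, "ggplot")
})
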