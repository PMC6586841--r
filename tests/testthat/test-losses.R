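test_that("distances match their closed forms", {
  expect_equal(embedding_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(embedding_distance(c(0, 0), c(3, 4), "manhattan"), 7)
  expect_equal(embedding_distance(c(0, 0), c(3, 4), "chebyshev"), 4)
  a <- rnorm(5)
  for (m in c("euclidean", "manhattan", "chebyshev")) {
    expect_equal(embedding_distance(a, a, m), 0)
    b <- rnorm(5)
    expect_equal(embedding_distance(a, b, m), embedding_distance(b, a, m))
  }
  expect_error(embedding_distance(1:3, 1:4), "dimensions")
})

test_that("pn loss reproduces hand-evaluated cases", {
  expect_equal(pn_loss(c(0, 0), c(0, 0), c(10, 0), margin = 0), 0)
  expect_equal(pn_loss(0, 1, 3, margin = 1), 0)    # 1 - min(3, 2) + 1
  expect_equal(pn_loss(0, 2, 1, margin = 0.5), 1.5) # 2 - min(1, 1) + 0.5
})

test_that("standard triplet loss reproduces hand-evaluated cases", {
  expect_equal(standard_triplet_loss(0, 1, 3, margin = 1), 0)
  expect_equal(standard_triplet_loss(0, 2, 1, margin = 0.5), 1.5)
  expect_equal(standard_triplet_loss(1, 1, 1, margin = 0), 0)
})

test_that("softmax-ratio loss hits its symmetric point and limits", {
  # equal distances: softmax mass 0.5 each -> (1-0.5)^2 + 0.5^2
  expect_equal(softmax_ratio_loss(c(0, 0), c(1, 0), c(0, 1)), 0.5)
  # distant negative: loss -> 0
  expect_lt(softmax_ratio_loss(c(0, 0), c(0, 0), c(100, 0)), 1e-10)
  # positive and negative roles are not symmetric
  near_p <- softmax_ratio_loss(c(0, 0), c(0, 0), c(5, 0))
  swapped <- softmax_ratio_loss(c(0, 0), c(5, 0), c(0, 0))
  expect_lt(near_p, swapped)
})

test_that("pn loss dominates the standard loss over random triplets", {
  set.seed(10)
  n <- 1e4
  ea <- matrix(rnorm(n * 3), n, 3)
  ep <- matrix(rnorm(n * 3), n, 3)
  en <- matrix(rnorm(n * 3), n, 3)
  for (m in c("euclidean", "manhattan", "chebyshev")) {
    l_pn <- pn_loss(ea, ep, en, metric = m)
    l_st <- standard_triplet_loss(ea, ep, en, metric = m)
    expect_true(all(l_pn >= l_st - 1e-12))
    # when D(p,n) >= D(a,n) the two coincide
    dan <- embedding_distance(ea, en, m)
    dpn <- embedding_distance(ep, en, m)
    same <- dpn >= dan
    expect_equal(l_pn[same], l_st[same])
  }
})

test_that("losses are invariant to rigid motions of the triplet", {
  set.seed(11)
  ea <- rnorm(2); ep <- rnorm(2); en <- rnorm(2)
  shift <- c(5, -3)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  for (kind in c("pn", "standard", "softmax_ratio", "softmax_ratio_pn")) {
    base <- triplet_loss(ea, ep, en, kind = kind)
    for (m in c("euclidean", "manhattan", "chebyshev")) {
      expect_equal(
        triplet_loss(ea + shift, ep + shift, en + shift, kind = kind, metric = m),
        triplet_loss(ea, ep, en, kind = kind, metric = m)
      )
    }
    # rotation invariance holds for the euclidean metric
    expect_equal(
      triplet_loss(drop(ea %*% rot), drop(ep %*% rot), drop(en %*% rot), kind = kind),
      base
    )
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(12)
  grads_checked <- 0
  while (grads_checked < 100) {
    ea <- rnorm(3); ep <- rnorm(3); en <- rnorm(3)
    for (kind in c("pn", "standard", "softmax_ratio", "softmax_ratio_pn")) {
      for (metric in c("euclidean", "manhattan", "chebyshev")) {
        dap <- embedding_distance(ea, ep, metric)
        dan <- embedding_distance(ea, en, metric)
        dpn <- embedding_distance(ep, en, metric)
        # skip kinks: hinge boundary, min ties, and (for chebyshev)
        # near-tied coordinate maxima where the metric itself is kinked
        if (abs(dap - min(dan, dpn) + 1) < 1e-2) next
        if (abs(dan - dpn) < 1e-2) next
        if (metric == "chebyshev") {
          near_tie <- any(vapply(list(ea - ep, ea - en, ep - en), function(d) {
            s <- sort(abs(d), decreasing = TRUE)
            s[1] - s[2] < 1e-2
          }, logical(1)))
          if (near_tie) next
        }
        if (metric == "manhattan") {
          near_zero <- any(abs(c(ea - ep, ea - en, ep - en)) < 1e-3)
          if (near_zero) next
        }
        g <- tripletembed:::triplet_loss_grad(ea, ep, en, kind = kind,
                                              metric = metric, margin = 1)
        f_of <- function(part) function(v) {
          args <- list(ea = ea, ep = ep, en = en)
          args[[part]] <- v
          triplet_loss(args$ea, args$ep, args$en, kind = kind,
                       metric = metric, margin = 1)
        }
        for (part in c("ea", "ep", "en")) {
          num <- numeric_gradient(f_of(part), get(part))
          ana <- drop(g[[paste0("d", part)]])
          expect_equal(ana, num, tolerance = 1e-5,
                       label = sprintf("%s/%s d%s", kind, metric, part))
        }
        grads_checked <- grads_checked + 1
      }
    }
  }
  expect_gte(grads_checked, 100)
})

test_that("the compiled kernel agrees with the R reference losses and gradients", {
  set.seed(13)
  n <- 500
  ea <- matrix(rnorm(n * 2), n, 2)
  ep <- matrix(rnorm(n * 2), n, 2)
  en <- matrix(rnorm(n * 2), n, 2)
  for (kind in c("pn", "standard", "softmax_ratio", "softmax_ratio_pn")) {
    for (metric in c("euclidean", "manhattan", "chebyshev")) {
      r_loss <- triplet_loss(ea, ep, en, kind = kind, metric = metric, margin = 1)
      c_loss <- drop(tripletembed:::.triplet_loss_batch_cpp(ea, ep, en, kind, metric, 1))
      expect_equal(c_loss, r_loss, tolerance = 1e-12)
      r_g <- tripletembed:::triplet_loss_grad(ea, ep, en, kind = kind,
                                              metric = metric, margin = 1)
      c_g <- tripletembed:::.triplet_grad_batch_cpp(ea, ep, en, kind, metric, 1)
      expect_equal(c_g$dea, unname(r_g$dea), tolerance = 1e-12)
      expect_equal(c_g$dep, unname(r_g$dep), tolerance = 1e-12)
      expect_equal(c_g$den, unname(r_g$den), tolerance = 1e-12)
    }
  }
})
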