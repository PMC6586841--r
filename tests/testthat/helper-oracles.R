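# Independent oracles used across test files.

# Exact k-nearest neighbours by full pairwise distance matrix (test oracle
# only; the package's production path is the approximate index).
brute_force_knn <- function(x, k) {
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  t(apply(d, 1, function(r) order(r)[seq_len(k)]))
}

mean_recall <- function(approx_idx, exact_idx) {
  k <- ncol(exact_idx)
  mean(vapply(seq_len(nrow(exact_idx)), function(i) {
    length(intersect(approx_idx[i, ], exact_idx[i, ])) / k
  }, numeric(1)))
}

# All permutations of 1..n (recursive enumeration; used for the exhaustive
# Mantel p-value oracle on small matrices).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  pos <- 1L
  for (s in sub) {
    for (i in seq_len(n)) {
      out[[pos]] <- append(s, n, after = i - 1L)
      pos <- pos + 1L
    }
  }
  out
}

# Central finite-difference gradient of f at x (vector-valued input).
numeric_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x))
    e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}
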