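# The triplet-loss family and its distance metrics.
#
# The headline loss ("pn" loss) modifies the standard triplet hinge by
# subtracting min(D(a,n), D(p,n)) instead of D(a,n) alone: the anchor-positive
# distance must undercut not just the anchor-negative distance but also the
# positive-negative distance, which empirically improves cluster separability
# without computing pairwise distances across a batch.  Distances are used
# un-squared, exactly as the metric definitions read.
#
# All loss functions here accept either single embedding vectors or matrices
# of stacked embeddings (one triplet per row) and return one loss value per
# triplet; the batch loss used in training is the arithmetic mean.  The
# matching *_grad functions return analytic gradients with respect to each of
# the three embeddings and are the reference the compiled training kernel is
# tested against.

LOSS_KINDS <- c("pn", "standard", "softmax_ratio", "softmax_ratio_pn")
LOSS_METRICS <- c("euclidean", "manhattan", "chebyshev")

as_embedding_rows <- function(v, arg) {
  if (is.null(dim(v))) matrix(v, nrow = 1) else as_feature_matrix(v, arg)
}

check_triplet_dims <- function(ea, ep, en) {
  if (!all(dim(ea) == dim(ep)) || !all(dim(ea) == dim(en))) {
    abort("Anchor, positive and negative embeddings must have equal dimensions.")
  }
}

#' Distance between embedded points
#'
#' Euclidean (`sqrt(sum((a-b)^2))`), Manhattan (`sum(|a-b|)`) or Chebyshev
#' (`max(|a-b|)`) distance, computed rowwise when matrices are given.
#'
#' @param a,b Numeric vectors, or matrices of matching shape (one point per
#'   row).
#' @param metric One of `"euclidean"`, `"manhattan"`, `"chebyshev"`.
#' @return Non-negative numeric vector, one value per row.
#' @export
#' @examples
#' embedding_distance(c(0, 0), c(3, 4))                    # 5
#' embedding_distance(c(0, 0), c(3, 4), "manhattan")       # 7
embedding_distance <- function(a, b, metric = c("euclidean", "manhattan", "chebyshev")) {
  metric <- match.arg(metric)
  a <- as_embedding_rows(a, "a")
  b <- as_embedding_rows(b, "b")
  if (!all(dim(a) == dim(b))) {
    abort("`a` and `b` must have the same dimensions.")
  }
  d <- a - b
  switch(metric,
    euclidean = sqrt(rowSums(d^2)),
    manhattan = rowSums(abs(d)),
    chebyshev = apply(abs(d), 1, max)
  )
}

# Rowwise gradient of D(a, b) with respect to `a` (gradient wrt b is its
# negative).  At D = 0 the subgradient 0 is used; Chebyshev ties route to the
# lowest coordinate index for determinism.
distance_grad <- function(a, b, metric) {
  d <- a - b
  switch(metric,
    euclidean = {
      dist <- sqrt(rowSums(d^2))
      g <- d / ifelse(dist > 0, dist, Inf)
      g
    },
    manhattan = sign(d),
    chebyshev = {
      g <- matrix(0, nrow(d), ncol(d))
      jmax <- apply(abs(d), 1, which.max)  # first (lowest) index on ties
      sel <- cbind(seq_len(nrow(d)), jmax)
      g[sel] <- sign(d[sel])
      g
    }
  )
}

#' Triplet loss with hardest-negative minimum ("pn" loss)
#'
#' `max(0, D(a,p) - min(D(a,n), D(p,n)) + m)` per triplet, where `m` is the
#' margin.  Compared with the standard triplet hinge this also demands the
#' positive sit further from the negative than it does from the anchor,
#' tightening cluster separation.  The batch loss is the mean over triplets.
#'
#' @param ea,ep,en Anchor, positive and negative embeddings: vectors or
#'   matrices of matching shape (one triplet per row).
#' @param metric Distance metric, see [embedding_distance()].
#' @param margin Non-negative margin `m` (default 1).
#' @return Non-negative numeric vector, one loss per triplet.
#' @export
#' @examples
#' pn_loss(0, 1, 3, margin = 1)   # 0
#' pn_loss(0, 2, 1, margin = 0.5) # 1.5
pn_loss <- function(ea, ep, en, metric = "euclidean", margin = 1) {
  metric <- match.arg(metric, LOSS_METRICS)
  check_positive_number(margin, "margin", strict = FALSE)
  ea <- as_embedding_rows(ea, "ea"); ep <- as_embedding_rows(ep, "ep")
  en <- as_embedding_rows(en, "en")
  check_triplet_dims(ea, ep, en)
  dap <- embedding_distance(ea, ep, metric)
  dan <- embedding_distance(ea, en, metric)
  dpn <- embedding_distance(ep, en, metric)
  pmax(0, dap - pmin(dan, dpn) + margin)
}

#' Standard triplet loss
#'
#' `max(0, D(a,p) - D(a,n) + m)` per triplet — the conventional hinge the
#' pn variant departs from.
#'
#' @inheritParams pn_loss
#' @return Non-negative numeric vector, one loss per triplet.
#' @export
standard_triplet_loss <- function(ea, ep, en, metric = "euclidean", margin = 1) {
  metric <- match.arg(metric, LOSS_METRICS)
  check_positive_number(margin, "margin", strict = FALSE)
  ea <- as_embedding_rows(ea, "ea"); ep <- as_embedding_rows(ep, "ep")
  en <- as_embedding_rows(en, "en")
  check_triplet_dims(ea, ep, en)
  dap <- embedding_distance(ea, ep, metric)
  dan <- embedding_distance(ea, en, metric)
  pmax(0, dap - dan + margin)
}

#' Softmax-ratio triplet loss
#'
#' With `(s_p, s_n) = softmax(-D(a,p), -D(a,x))` the loss is
#' `(1 - s_p)^2 + s_n^2`, driving the softmax mass onto the positive.  The
#' plain variant uses `x = n`; the pn variant replaces `D(a,n)` with
#' `min(D(a,n), D(p,n))`.  This form follows the triplet-network convention
#' the loss is conventionally attributed to; it is provided for completeness
#' of the loss family and is not the recommended default.
#'
#' @inheritParams pn_loss
#' @param pn Logical; use the hardest-negative minimum variant?
#' @return Numeric vector in `[0, 2]`, one loss per triplet.
#' @export
softmax_ratio_loss <- function(ea, ep, en, metric = "euclidean", pn = FALSE) {
  metric <- match.arg(metric, LOSS_METRICS)
  ea <- as_embedding_rows(ea, "ea"); ep <- as_embedding_rows(ep, "ep")
  en <- as_embedding_rows(en, "en")
  check_triplet_dims(ea, ep, en)
  dap <- embedding_distance(ea, ep, metric)
  dan <- embedding_distance(ea, en, metric)
  dx <- if (pn) pmin(dan, embedding_distance(ep, en, metric)) else dan
  sn <- stats::plogis(dap - dx)    # softmax component on the negative
  sp <- 1 - sn
  (1 - sp)^2 + sn^2
}

#' Evaluate a named loss from the loss family
#'
#' Dispatch helper used by the trainer and the command-line interface: the
#' four kinds are `"pn"`, `"standard"`, `"softmax_ratio"` and
#' `"softmax_ratio_pn"`, each combinable with the three metrics.
#'
#' @inheritParams pn_loss
#' @param kind Loss kind, one of `r paste0('"', LOSS_KINDS, '"', collapse = ", ")`.
#' @return Numeric vector of per-triplet losses.
#' @export
triplet_loss <- function(ea, ep, en, kind = "pn", metric = "euclidean", margin = 1) {
  kind <- match.arg(kind, LOSS_KINDS)
  switch(kind,
    pn = pn_loss(ea, ep, en, metric, margin),
    standard = standard_triplet_loss(ea, ep, en, metric, margin),
    softmax_ratio = softmax_ratio_loss(ea, ep, en, metric, pn = FALSE),
    softmax_ratio_pn = softmax_ratio_loss(ea, ep, en, metric, pn = TRUE)
  )
}

# Analytic gradients of the per-triplet losses with respect to (ea, ep, en).
# Subgradient conventions: hinge at exactly 0 -> 0; ties in the
# min(D(a,n), D(p,n)) term route to the D(a,n) branch.  Returns a list of
# three matrices matching the inputs.
triplet_loss_grad <- function(ea, ep, en, kind = "pn", metric = "euclidean",
                              margin = 1) {
  kind <- match.arg(kind, LOSS_KINDS)
  metric <- match.arg(metric, LOSS_METRICS)
  ea <- as_embedding_rows(ea, "ea"); ep <- as_embedding_rows(ep, "ep")
  en <- as_embedding_rows(en, "en")
  check_triplet_dims(ea, ep, en)

  dap <- embedding_distance(ea, ep, metric)
  dan <- embedding_distance(ea, en, metric)
  dpn <- embedding_distance(ep, en, metric)
  g_ap <- distance_grad(ea, ep, metric)  # dD(a,p)/dea; wrt ep it is -g_ap
  g_an <- distance_grad(ea, en, metric)
  g_pn <- distance_grad(ep, en, metric)
  use_an <- dan <= dpn                   # tie -> anchor-negative branch

  zero <- matrix(0, nrow(ea), ncol(ea))
  if (kind %in% c("pn", "standard")) {
    if (kind == "standard") use_an <- rep(TRUE, length(dan))
    dmin <- ifelse(use_an, dan, dpn)
    active <- (dap - dmin + margin) > 0
    w <- as.numeric(active)
    wan <- w * as.numeric(use_an)
    wpn <- w * as.numeric(!use_an)
    list(
      dea = w * g_ap - wan * g_an,
      dep = -w * g_ap - wpn * g_pn,
      den = wan * g_an + wpn * g_pn
    )
  } else {
    pn <- kind == "softmax_ratio_pn"
    if (!pn) use_an <- rep(TRUE, length(dan))
    dx <- ifelse(use_an, dan, dpn)
    sn <- stats::plogis(dap - dx)
    # loss = 2 * sn^2; d loss / d(dap - dx) = 4 sn^2 (1 - sn)
    w <- 4 * sn^2 * (1 - sn)
    wan <- w * as.numeric(use_an)
    wpn <- w * as.numeric(!use_an)
    list(
      dea = w * g_ap - wan * g_an,
      dep = -w * g_ap - wpn * g_pn,
      den = wan * g_an + wpn * g_pn
    )
  }
}
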