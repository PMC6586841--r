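---
title: "Structure-preserving embeddings with siamese triplet networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-preserving embeddings with siamese triplet networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`tripletembed` learns a parametric map $f_\theta : \mathbb{R}^D \to
\mathbb{R}^d$ (typically $d = 2$) that preserves both the local
neighbourhood structure and the global inter-cluster geometry of a numeric
observations-by-features table — single-cell mass-cytometry intensities,
PCA-compressed scRNA-seq expression, or any comparable matrix.

The map is a small dense network: three hidden layers of 128 SELU units
followed by a linear embedding head.  The SELU activation

$$\mathrm{selu}(x) = \lambda \begin{cases} x & x > 0 \\
\alpha e^x - \alpha & x \le 0 \end{cases},
\qquad \alpha = 1.6733,\; \lambda = 1.0507$$

is self-normalising: with LeCun-normal initialisation
($\sigma^2 = 1/\mathrm{fan_{in}}$), activation means and variances stay
near 0 and 1 through depth, which removes the need for batch
normalisation.  Regularisation uses *alpha dropout*: dropped units are set
to the SELU saturation value $-\lambda\alpha$ (not zero) and an affine
correction restores the layer's mean and variance in expectation, so the
self-normalising property survives dropout.  The linear head is
Glorot-uniform initialised and carries a bias (a harmless translation
freedom; embeddings are in any case only defined up to rigid motions).

Training is *siamese*: three copies of this one network embed an anchor
$a$, a positive $p$ and a negative $n$, and the loss compares the three
embeddings.  There is exactly one set of weights; "branches" are just
three forward passes through it.

## The pn triplet loss

With $D_{u,v}$ the Euclidean distance between embedded points, the
training loss per triplet is

$$L = \big[\, D_{a,p} - \min(D_{a,n},\, D_{p,n}) + m \,\big]_+$$

The difference from the standard triplet hinge
$[D_{a,p} - D_{a,n} + m]_+$ is the $\min$: the anchor–positive distance
must undercut *both* the anchor–negative and the positive–negative
distance.  Since $\min(D_{a,n}, D_{p,n}) \le D_{a,n}$, the pn loss
dominates the standard loss pointwise; it penalises configurations where
the positive drifts towards the negative even when the anchor itself is
well placed.  The batch loss is the arithmetic mean over triplets, and the
last incomplete minibatch of an epoch is kept (mean reduction makes this
size-consistent).

Manhattan and Chebyshev variants of $D$, and a softmax-ratio loss family,
are selectable (`loss`, `metric` arguments); Euclidean pn is the default
and the recommended choice.  Distances enter the loss un-squared.  The
softmax-ratio form used is $(1-s_p)^2 + s_n^2$ with
$(s_p, s_n) = \mathrm{softmax}(-D_{a,p}, -D_{a,x})$, the conventional
triplet-network formulation; it is provided for completeness of the loss
family rather than as a recommended setting.

Subgradient conventions (relevant at the loss's kinks, and fixed for
determinism): the hinge contributes zero gradient exactly at the boundary;
ties in the $\min$ route the gradient to the anchor–negative branch;
Chebyshev ties route to the lowest coordinate index; a zero distance
contributes zero gradient.

## Triplet mining from the KNN graph

An approximate k-nearest-neighbour index (Annoy random-projection trees,
Euclidean metric) is built once on the (preprocessed) input, never rebuilt
during training.  Each epoch draws exactly one triplet per observation:
the anchor's positive is uniform over its $k$ neighbour list, the negative
uniform (by rejection) over all rows outside the list.  Positives thus
encode local structure while negatives are global, and resampling every
epoch means the network sees a fresh view of both at $\Theta(n)$ cost per
epoch — this is what keeps overall training linear in $n$, in contrast to
methods that need pairwise distances within a batch or across the data.

Parameters that matter:

* `k` (neighbourhood size) — default 1% of $n$, clamped to $[2, 150]$.
  Accuracy is broadly stable over a wide band of $k$; the 1% rule sits in
  the middle of it, and the cap keeps memory linear for very large inputs.
  A row is never its own neighbour (otherwise anchor and positive could
  coincide); distance ties break to the lower row index so results are
  reproducible.
* `margin` $m$ — default 1.  Embedding shape is retained over roughly
  $m \in [0.1, 500]$; very large margins progressively collapse the two
  embedding dimensions onto each other and eventually cause exploding
  gradients.  A non-finite epoch loss aborts with an error naming the
  epoch and margin rather than returning garbage.
* `n_trees` (default 50) and `search_k` (default: Annoy's own heuristic) —
  recall/cost trade-off of the approximate index.  The exact-KNN oracle is
  used only in tests.
* `batch_size` 128, Adam with learning rate $10^{-3}$,
  $\beta_1 = 0.9$, $\beta_2 = 0.999$; at most 1000 epochs with early
  stopping after 50 epochs without a new best training loss.  No
  validation split is used — the loss is a sampling-noisy statistic and
  the patience window absorbs that noise.  Early stopping keeps the
  last-epoch weights (the monitored quantity is noisy, so "best epoch"
  weights would be selected on noise).

Negatives are resampled per epoch (not per batch); with one triplet per
anchor this keeps an epoch a single pass over the data.  Rejection
sampling of negatives degrades as $k$ approaches $n$, so fitting requires
$n > k + 1$.

## Preprocessing

Two transforms are built in, matching field practice, and are recorded in
the fitted model so `predict()` replays them identically on new data:

* `arcsinh_transform()` — $\mathrm{asinh}(x/c)$ with cofactor $c = 5$, the
  standard variance-stabilisation for mass-cytometry intensities.
* `pca_reduce()` — projection onto the leading principal components
  (default 50), the usual noise-reduction step for scRNA-seq before
  embedding.  Exact SVD is used up to $10^5$ rows and a truncated Lanczos
  solver above that (the decomposition is a preprocessing step, not an
  inferential target).  Out-of-sample rows are projected with the
  *training* loadings, never refit.

Nothing else is applied implicitly: no feature scaling, no log transform,
no library-size normalisation.  Silent rescaling would change the
distances the loss consumes.  Non-finite values are a hard error
everywhere — triplet distances are meaningless with missing data, so
imputation is refused rather than improvised.  Labels travel as a separate
vector argument beside the matrix (the R idiom), used only by the
evaluation protocol, never by training.

## Evaluating structure preservation

The package ships the matching evaluation protocol rather than leaving it
to ad-hoc scripts:

* `centroid_distances()` — per-cluster mean vectors and their Euclidean
  distance matrix, clusters in sorted label order (at least 3 clusters, or
  the test below has no degrees of freedom).
* `mantel_test()` — Pearson correlation of the strictly-upper triangles of
  two such matrices, with a permutation p-value
  $(1 + \#\{|r_{perm}| \ge |r_{obs}|\})/(1 + n_{perm})$: two-sided,
  999 permutations by default, never exactly zero.
* `structure_benchmark()` — repeats the comparison over random subsamples
  drawn without replacement (a subsample that loses a cluster is redrawn,
  with a message), producing a correlation distribution per embedding
  method; distributions are summarised by median *and* mean and compared
  pairwise with a two-tailed t-test (the t-test compares means; medians
  are more robust for skewed correlation distributions, so both are
  reported).  Any function from a data matrix to an embedding can be
  plugged in as a method — a fitted model's transform, PCA, or an external
  t-SNE wrapper.  Cluster labels are an input; clustering itself
  (e.g. phenograph on unlabelled data) is deliberately out of scope, with
  any external cluster-assignment function usable upstream.
* `extrapolation_experiment()` — fit on a random subset, train a
  classifier (default: random forest) on the subset's embedding and
  labels, embed the held-out rows with the parametric map, and score the
  classifier's predictions (micro accuracy, with row-normalisable
  confusion matrices).  This measures whether the learned map, not just
  the training embedding, is class-faithful.
* `stability_across_runs()` — refit under independent seeds and compare
  label-centroid geometry between runs pairwise; the minimum pairwise
  correlation summarises worst-case run-to-run drift from the method's
  stochastic ingredients (tree construction, initialisation, triplet
  draws, dropout).
* `hopkins_statistic()` — clustering tendency, $\approx 0.5$ for
  spatially random data, $\to 1$ for compact well-separated clusters.
  Probes are drawn uniformly over the **convex hull** of 2-D point clouds
  rather than the bounding box.  This is deliberate: embeddings are only
  defined up to rigid motions, and box probing is not rotation invariant —
  a uniform square rotated 45° is scored as strongly clustered under the
  box convention purely from its empty box corners, which would make the
  statistic useless for judging embeddings.  Hull probing scores that
  rotation near 0.5 while still scoring genuinely clustered layouts well
  above it.  For inputs with more than two columns the bounding box is
  used (hull sampling is impractical) and the same caveat applies.

## Synthetic benchmarks

Three planar generators with a deterministic nine-dimensional polynomial
lift $(x+y,\; x-y,\; xy,\; x^2,\; y^2,\; x^2y,\; xy^2,\; x^3,\; y^3)$
give high-dimensional inputs whose ground-truth 2-D structure is known
exactly:

* `generate_uniform()` — i.i.d. uniform noise on the unit square.  An
  embedding of its lift should *stay* unclustered; methods that fabricate
  compact clusters from noise fail here.
* `generate_cassini()` — two banana-shaped bands enclosing a central disc
  (three clusters with meaningful relative geometry).
* `generate_smiley()` — two Gaussian eyes, a uniform trapezoid nose, a
  parabola mouth with vertical Gaussian jitter (four parts of varying
  shape, scale and density).

Shape constants follow the classic conventions for these datasets and
live in one config block; the evaluation properties depend only on
topology (number of parts, relative centroid positions), not on the exact
constants.  Default size is $n = 5000$ per dataset.

What these benchmarks do *not* emulate: count noise, dropout/zero
inflation, batch effects, heavy-tailed marker distributions, or imbalanced
rare populations.  Passing them demonstrates that the optimiser and loss
recover known low-dimensional geometry through a polynomial lift — it
does not certify behaviour on any particular real single-cell dataset,
where preprocessing choices and cluster definitions dominate.

## Determinism and numerical choices

Every stochastic stage (index build, weight initialisation, per-epoch
triplet draws, dropout masks, subsampling) draws a child seed from the one
user-supplied seed, so a fit is bitwise reproducible in single-threaded
BLAS mode; multi-threaded BLAS guarantees statistical, not bitwise,
reproducibility.  The minibatch numerics run in a compiled kernel whose
losses and gradients are tested for exact agreement with the plain-R
reference implementations, and the analytic gradients are checked against
central finite differences away from the loss's kinks.  Adam uses
$\epsilon = 10^{-8}$.  Model files round-trip exactly and carry a format
version string that is checked on load.

Problem sizes used by the test suite and the acceptance script (the
package's own choices, balancing statistical resolution against runtime):
structure preservation and stability on Smiley-9D at $n = 5000$ with 5–10
independent fits at default training settings; noise honesty at
$n = 5000$; extrapolation from 1000 of 10\,000 Cassini-9D points;
neighbour recall at $n = 2000$ against an exact oracle; and the scaling
sweep over $n \in \{2000, \dots, 32000\}$ at 32 input dimensions with 20
fixed epochs.  In the scaling sweep $k$ is held fixed at 150 across sizes
so the per-row workload is constant and the log–log slope isolates the
dependence on $n$; letting $k$ follow its adaptive default would conflate
the neighbourhood policy with the complexity being measured.

## Known limitations

* The embedding scale and orientation are arbitrary; only relative
  geometry is meaningful.  All shipped evaluation measures are invariant
  to rigid motions accordingly.
* Very large margins ($m \gtrsim 500$) can destabilise training; the fit
  aborts on non-finite loss rather than silently degrading.
* The approximate index trades recall for speed; at default settings
  recall against the exact oracle is well above 0.9 on realistic
  geometries, but adversarial inputs (e.g. near-duplicate points at scale)
  can lower it.  Raising `n_trees`/`search_k` recovers exactness at cost.
* Binary FCS parsing, library-size normalisation pipelines, clustering of
  unlabelled data, and GPU/distributed training are out of scope.
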