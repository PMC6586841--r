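// Minibatch training kernel for the siamese triplet network.
//
// One call runs one epoch: for each minibatch, the anchor/positive/negative
// rows are stacked and pushed through the shared-weight encoder once,
// per-triplet loss gradients are formed at the embedding layer, and the
// gradient is backpropagated and applied with Adam.  The epoch's triplets
// are sampled on the R side (so the sampling scheme has a single, tested
// implementation); only the numerics live here.
//
// The forward pass fuses the SELU activation, the alpha-dropout mask and
// the backward-pass multiplier (SELU derivative x dropout scaling) into one
// sweep over each layer, so the backward pass needs no exp() calls and no
// stored masks.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double SELU_ALPHA = 1.6733;
static const double SELU_LAMBDA = 1.0507;

enum LossKind { PN, STANDARD, SOFTMAX_RATIO, SOFTMAX_RATIO_PN };
enum Metric { EUCLIDEAN, MANHATTAN, CHEBYSHEV };

static LossKind parse_kind(const std::string& s) {
  if (s == "pn") return PN;
  if (s == "standard") return STANDARD;
  if (s == "softmax_ratio") return SOFTMAX_RATIO;
  if (s == "softmax_ratio_pn") return SOFTMAX_RATIO_PN;
  stop("unknown loss kind '%s'", s);
}

static Metric parse_metric(const std::string& s) {
  if (s == "euclidean") return EUCLIDEAN;
  if (s == "manhattan") return MANHATTAN;
  if (s == "chebyshev") return CHEBYSHEV;
  stop("unknown metric '%s'", s);
}

// xorshift128+ — fast uniform doubles for the dropout masks; seeded per
// epoch from the R-side seed stream so runs stay reproducible.
struct FastRng {
  uint64_t s0, s1;
  explicit FastRng(uint64_t seed) {
    // splitmix64 seeding
    auto next = [&seed]() {
      uint64_t z = (seed += 0x9e3779b97f4a7c15ULL);
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      return z ^ (z >> 31);
    };
    s0 = next();
    s1 = next();
  }
  inline double uniform() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return static_cast<double>((s1 + y) >> 11) * (1.0 / 9007199254740992.0);
  }
};

// Rowwise distance and gradient d D(a,b) / d a.  Gradient wrt b is -grad.
static void row_distance(const arma::mat& a, const arma::mat& b, Metric metric,
                         arma::vec& dist, arma::mat& grad) {
  arma::mat d = a - b;
  switch (metric) {
  case EUCLIDEAN: {
    dist = arma::sqrt(arma::sum(arma::square(d), 1));
    grad = d;
    for (arma::uword i = 0; i < d.n_rows; ++i) {
      if (dist(i) > 0) grad.row(i) /= dist(i); else grad.row(i).zeros();
    }
    break;
  }
  case MANHATTAN: {
    dist = arma::sum(arma::abs(d), 1);
    grad = arma::sign(d);
    break;
  }
  case CHEBYSHEV: {
    dist.set_size(d.n_rows);
    grad.zeros(d.n_rows, d.n_cols);
    for (arma::uword i = 0; i < d.n_rows; ++i) {
      arma::rowvec ad = arma::abs(d.row(i));
      arma::uword j = ad.index_max();  // first (lowest) index on ties
      dist(i) = ad(j);
      grad(i, j) = d(i, j) > 0 ? 1.0 : (d(i, j) < 0 ? -1.0 : 0.0);
    }
    break;
  }
  }
}

// Per-triplet losses and gradients at the embedding layer.
static arma::vec loss_and_grads(const arma::mat& ea, const arma::mat& ep,
                                const arma::mat& en, LossKind kind,
                                Metric metric, double margin,
                                arma::mat& dea, arma::mat& dep, arma::mat& den) {
  arma::vec dap, dan, dpn;
  arma::mat gap, gan, gpn;
  row_distance(ea, ep, metric, dap, gap);
  row_distance(ea, en, metric, dan, gan);
  row_distance(ep, en, metric, dpn, gpn);

  const arma::uword m = ea.n_rows;
  arma::vec loss(m);
  dea.zeros(arma::size(ea));
  dep.zeros(arma::size(ea));
  den.zeros(arma::size(ea));

  for (arma::uword i = 0; i < m; ++i) {
    bool use_an = true;
    double dmin = dan(i);
    if (kind == PN || kind == SOFTMAX_RATIO_PN) {
      if (dpn(i) < dan(i)) { use_an = false; dmin = dpn(i); }  // tie -> a,n
    }
    double w;  // d loss / d (dap - dmin)
    if (kind == PN || kind == STANDARD) {
      double l = dap(i) - dmin + margin;
      loss(i) = l > 0 ? l : 0.0;
      w = l > 0 ? 1.0 : 0.0;
    } else {
      double sn = 1.0 / (1.0 + std::exp(-(dap(i) - dmin)));
      loss(i) = 2.0 * sn * sn;
      w = 4.0 * sn * sn * (1.0 - sn);
    }
    if (w != 0.0) {
      dea.row(i) += w * gap.row(i);
      dep.row(i) -= w * gap.row(i);
      if (use_an) {
        dea.row(i) -= w * gan.row(i);
        den.row(i) += w * gan.row(i);
      } else {
        dep.row(i) -= w * gpn.row(i);
        den.row(i) += w * gpn.row(i);
      }
    }
  }
  return loss;
}

// Per-triplet loss values for a batch of embeddings; exposed so tests can
// verify the kernel agrees with the R reference implementation.
// [[Rcpp::export(name = ".triplet_loss_batch_cpp")]]
arma::vec triplet_loss_batch_cpp(const arma::mat& ea, const arma::mat& ep,
                                 const arma::mat& en, std::string kind,
                                 std::string metric, double margin) {
  arma::mat dea, dep, den;
  return loss_and_grads(ea, ep, en, parse_kind(kind), parse_metric(metric),
                        margin, dea, dep, den);
}

// Gradients at the embedding layer; exposed for parity tests against the R
// reference gradients.
// [[Rcpp::export(name = ".triplet_grad_batch_cpp")]]
List triplet_grad_batch_cpp(const arma::mat& ea, const arma::mat& ep,
                            const arma::mat& en, std::string kind,
                            std::string metric, double margin) {
  arma::mat dea, dep, den;
  loss_and_grads(ea, ep, en, parse_kind(kind), parse_metric(metric), margin,
                 dea, dep, den);
  return List::create(Named("dea") = dea, Named("dep") = dep,
                      Named("den") = den);
}

// In-place Adam step over one parameter block.
static inline void adam_update(arma::mat& w, arma::mat& mw, arma::mat& vw,
                               const arma::mat& g, double lr, double beta1,
                               double beta2, double eps, double bc1,
                               double bc2) {
  double* wp = w.memptr();
  double* mp = mw.memptr();
  double* vp = vw.memptr();
  const double* gp = g.memptr();
  const arma::uword n = w.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    mp[i] = beta1 * mp[i] + (1.0 - beta1) * gp[i];
    vp[i] = beta2 * vp[i] + (1.0 - beta2) * gp[i] * gp[i];
    wp[i] -= lr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + eps);
  }
}

// One training epoch.  `weights`/`biases` and the Adam moment lists are
// modified copies returned to R; `triplets` is a 3-column 0-based integer
// matrix (anchor, positive, negative).  Returns the mean per-triplet loss
// over the epoch and the updated state.
// [[Rcpp::export(name = ".run_epoch_cpp")]]
List run_epoch_cpp(List weights, List biases, List m_w, List v_w, List m_b,
                   List v_b, int adam_t, const arma::mat& X,
                   const arma::imat& triplets, int batch_size,
                   std::string loss_kind, std::string metric, double margin,
                   double lr, double beta1, double beta2, double eps,
                   double dropout_rate, int mask_seed) {
  const LossKind kind = parse_kind(loss_kind);
  const Metric met = parse_metric(metric);
  const int L = weights.size();
  std::vector<arma::mat> W(L), mW(L), vW(L);
  std::vector<arma::rowvec> b(L), mB(L), vB(L);
  for (int l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(weights[l]);
    b[l] = as<arma::rowvec>(biases[l]);
    mW[l] = as<arma::mat>(m_w[l]);
    vW[l] = as<arma::mat>(v_w[l]);
    mB[l] = as<arma::rowvec>(m_b[l]);
    vB[l] = as<arma::rowvec>(v_b[l]);
  }

  FastRng rng(static_cast<uint64_t>(static_cast<uint32_t>(mask_seed)));

  // Alpha-dropout constants: dropped units go to the SELU saturation value,
  // then an affine correction restores mean/variance in expectation.
  const double ap = -SELU_LAMBDA * SELU_ALPHA;
  const double q = 1.0 - dropout_rate;
  const double dscale = dropout_rate > 0
    ? 1.0 / std::sqrt(q + ap * ap * q * dropout_rate) : 1.0;
  const double dshift = -dscale * ap * dropout_rate;

  const arma::uword n_tri = triplets.n_rows;
  double loss_sum = 0.0;

  // A[l]: layer inputs (post-dropout); G[l]: backward multiplier
  // selu'(z) * dropout scale, zero where dropped.
  std::vector<arma::mat> A(L + 1), G(L - 1);
  arma::mat Z, dZ, delta, dea, dep, den;

  for (arma::uword start = 0; start < n_tri; start += batch_size) {
    const arma::uword end = std::min<arma::uword>(start + batch_size, n_tri) - 1;
    const arma::uword m = end - start + 1;

    // Stack anchor, positive, negative rows into one 3m x d input.
    A[0].set_size(3 * m, X.n_cols);
    for (arma::uword i = 0; i < m; ++i) {
      A[0].row(i)         = X.row(triplets(start + i, 0));
      A[0].row(m + i)     = X.row(triplets(start + i, 1));
      A[0].row(2 * m + i) = X.row(triplets(start + i, 2));
    }

    // Forward pass: dense -> fused selu/alpha-dropout per hidden layer,
    // linear head.
    for (int l = 0; l < L - 1; ++l) {
      Z = A[l] * W[l];
      Z.each_row() += b[l];
      A[l + 1].set_size(arma::size(Z));
      G[l].set_size(arma::size(Z));
      const double* zp = Z.memptr();
      double* ap_out = A[l + 1].memptr();
      double* gp = G[l].memptr();
      const arma::uword ne = Z.n_elem;
      if (dropout_rate > 0) {
        for (arma::uword j = 0; j < ne; ++j) {
          const double z = zp[j];
          double s, der;
          if (z > 0) { s = SELU_LAMBDA * z; der = SELU_LAMBDA; }
          else { const double e = std::exp(z);
                 s = SELU_LAMBDA * SELU_ALPHA * (e - 1.0);
                 der = SELU_LAMBDA * SELU_ALPHA * e; }
          if (rng.uniform() < dropout_rate) {
            ap_out[j] = dscale * ap + dshift;
            gp[j] = 0.0;
          } else {
            ap_out[j] = dscale * s + dshift;
            gp[j] = dscale * der;
          }
        }
      } else {
        for (arma::uword j = 0; j < ne; ++j) {
          const double z = zp[j];
          if (z > 0) { ap_out[j] = SELU_LAMBDA * z; gp[j] = SELU_LAMBDA; }
          else { const double e = std::exp(z);
                 ap_out[j] = SELU_LAMBDA * SELU_ALPHA * (e - 1.0);
                 gp[j] = SELU_LAMBDA * SELU_ALPHA * e; }
        }
      }
    }
    arma::mat E = A[L - 1] * W[L - 1];
    E.each_row() += b[L - 1];

    arma::vec loss = loss_and_grads(E.rows(0, m - 1), E.rows(m, 2 * m - 1),
                                    E.rows(2 * m, 3 * m - 1), kind, met,
                                    margin, dea, dep, den);
    if (!loss.is_finite()) {
      return List::create(Named("ok") = false, Named("loss") = NA_REAL);
    }
    loss_sum += arma::accu(loss);

    // Mean reduction over the batch.
    delta = arma::join_cols(dea, dep, den) / static_cast<double>(m);

    // Backward pass with Adam updates.
    ++adam_t;
    const double bc1 = 1.0 - std::pow(beta1, adam_t);
    const double bc2 = 1.0 - std::pow(beta2, adam_t);
    for (int l = L - 1; l >= 0; --l) {
      if (l == L - 1) {
        dZ = delta;
      } else {
        dZ = delta % G[l];
      }
      arma::mat gW = A[l].t() * dZ;
      arma::rowvec gB = arma::sum(dZ, 0);
      if (l > 0) delta = dZ * W[l].t();

      adam_update(W[l], mW[l], vW[l], gW, lr, beta1, beta2, eps, bc1, bc2);
      {
        double* bp = b[l].memptr();
        double* mp = mB[l].memptr();
        double* vp = vB[l].memptr();
        const double* gp = gB.memptr();
        for (arma::uword i = 0; i < b[l].n_elem; ++i) {
          mp[i] = beta1 * mp[i] + (1.0 - beta1) * gp[i];
          vp[i] = beta2 * vp[i] + (1.0 - beta2) * gp[i] * gp[i];
          bp[i] -= lr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + eps);
        }
      }
    }
  }

  List outW(L), outB(L), outMW(L), outVW(L), outMB(L), outVB(L);
  for (int l = 0; l < L; ++l) {
    outW[l] = W[l];
    outB[l] = NumericVector(b[l].begin(), b[l].end());
    outMW[l] = mW[l];
    outVW[l] = vW[l];
    outMB[l] = NumericVector(mB[l].begin(), mB[l].end());
    outVB[l] = NumericVector(vB[l].begin(), vB[l].end());
  }
  return List::create(
    Named("ok") = true,
    Named("loss") = loss_sum / static_cast<double>(n_tri),
    Named("weights") = outW, Named("biases") = outB,
    Named("m_w") = outMW, Named("v_w") = outVW,
    Named("m_b") = outMB, Named("v_b") = outVB,
    Named("adam_t") = adam_t);
}
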