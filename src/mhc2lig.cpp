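// Low-level kernels for peptide encoding, the two-output shallow network,
// binding-core search and online training. Feature layout must stay in sync
// with the R-level encode_instance():
//   [0..179]    9 x 20 core block (position-major)
//   [180..199]  N-side PFR mean composition (up to pfr_window residues
//               adjacent to the core)
//   [200]       N flank length, min(len, pfr_window)/pfr_window
//   [201..220]  C-side PFR mean composition
//   [221]       C flank length feature
//   [222..230]  one-hot length bins for lengths 11..19 (clamped)
//   [231..470]  optional 12 x 20 context block (N-context, N-terminal
//               peptide, C-context, C-terminal peptide; zero for wildcards)
// The context block does not depend on the core offset, so it is stored
// once per instance (CTX x n) while the offset-dependent base block is
// stored once per (instance, offset) column (BASE x total_offsets); the
// network weight matrix is laid out [base | context] per hidden unit.
// Residues are coded 1..20 in the package alphabet order; 0 is the 'X'
// wildcard and contributes an all-zero 20-vector.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int CORE = 9;
static const int BASE_DIM = 9 * 20 + 21 + 21 + 9; // 231
static const int CTX_DIM = 12 * 20;               // 240

static inline double sigm(double z) { return 1.0 / (1.0 + std::exp(-z)); }

static void encode_base(const int* pep, int L, int off, const double* bl,
                        int pfrw, double* out) {
  std::fill(out, out + BASE_DIM, 0.0);
  for (int k = 0; k < CORE; ++k) {
    int r = pep[off + k];
    if (r > 0) {
      const int b = k * 20;
      for (int a = 0; a < 20; ++a) out[b + a] = bl[(r - 1) + 20 * a];
    }
  }
  // N-side flank: mean encoding of the pfr_window residues adjacent to core
  int nf = off;
  int take = nf < pfrw ? nf : pfrw;
  if (take > 0) {
    for (int k = off - take; k < off; ++k) {
      int r = pep[k];
      if (r > 0)
        for (int a = 0; a < 20; ++a) out[180 + a] += bl[(r - 1) + 20 * a];
    }
    for (int a = 0; a < 20; ++a) out[180 + a] /= take;
  }
  out[200] = (double)take / (double)pfrw;
  // C-side flank
  int cf = L - CORE - off;
  take = cf < pfrw ? cf : pfrw;
  if (take > 0) {
    for (int k = off + CORE; k < off + CORE + take; ++k) {
      int r = pep[k];
      if (r > 0)
        for (int a = 0; a < 20; ++a) out[201 + a] += bl[(r - 1) + 20 * a];
    }
    for (int a = 0; a < 20; ++a) out[201 + a] /= take;
  }
  out[221] = (double)take / (double)pfrw;
  // length bins, clamped to 11..19 for prediction-time lengths
  int Lb = L < 11 ? 11 : (L > 19 ? 19 : L);
  out[222 + (Lb - 11)] = 1.0;
}

static void encode_ctx(const int* ctx12, const double* bl, double* out) {
  std::fill(out, out + CTX_DIM, 0.0);
  for (int j = 0; j < 12; ++j) {
    int r = ctx12[j];
    if (r > 0) {
      const int b = j * 20;
      for (int a = 0; a < 20; ++a) out[b + a] = bl[(r - 1) + 20 * a];
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_encode_features(IntegerVector pep, int offset,
                                  IntegerVector ctx12, NumericMatrix bl,
                                  bool context_mode, int pfr_window) {
  int L = pep.size();
  if (L < CORE) stop("peptide shorter than the 9-residue core");
  if (offset < 0 || offset > L - CORE) stop("core offset out of range");
  int D = BASE_DIM + (context_mode ? CTX_DIM : 0);
  NumericVector out(D);
  std::vector<int> p(pep.begin(), pep.end());
  encode_base(p.data(), L, offset, bl.begin(), pfr_window, out.begin());
  if (context_mode) {
    std::vector<int> c(ctx12.begin(), ctx12.end());
    encode_ctx(c.data(), bl.begin(), out.begin() + BASE_DIM);
  }
  return out;
}

// Encode every core offset of every instance: base block per column,
// context block per instance (zero-row matrix when context is off).
// [[Rcpp::export]]
List cpp_precompute(List peps, IntegerMatrix ctx, NumericMatrix bl,
                    bool context_mode, int pfr_window, LogicalVector hydro) {
  int n = peps.size();
  IntegerVector col_start(n), n_off(n);
  R_xlen_t total = 0;
  std::vector<IntegerVector> pv(n);
  for (int i = 0; i < n; ++i) {
    pv[i] = as<IntegerVector>(peps[i]);
    int L = pv[i].size();
    if (L < CORE) stop("peptide %d is shorter than 9 residues", i + 1);
    col_start[i] = (int)total;
    n_off[i] = L - CORE + 1;
    total += n_off[i];
  }
  NumericMatrix feat(BASE_DIM, (int)total);
  NumericMatrix cfeat(context_mode ? CTX_DIM : 0, n);
  LogicalVector p1h((int)total);
  int c12[12];
  for (int i = 0; i < n; ++i) {
    const int* pep = pv[i].begin();
    int L = pv[i].size();
    if (context_mode) {
      for (int j = 0; j < 12; ++j) c12[j] = ctx(i, j);
      encode_ctx(c12, bl.begin(), &cfeat(0, i));
    }
    for (int k = 0; k < n_off[i]; ++k) {
      int col = col_start[i] + k;
      encode_base(pep, L, k, bl.begin(), pfr_window, &feat(0, col));
      int r = pep[k];
      p1h[col] = (r > 0) && hydro[r - 1];
    }
  }
  return List::create(_["features"] = feat, _["ctx_features"] = cfeat,
                      _["col_start"] = col_start, _["n_off"] = n_off,
                      _["p1_hydro"] = p1h,
                      _["dim"] = BASE_DIM + (context_mode ? CTX_DIM : 0));
}

// Four-way unrolled dot product: keeps the reduction vectorisable without
// reassociating a single accumulator.
static inline double dot(const double* __restrict w, const double* __restrict x,
                         int D) {
  double s0 = 0, s1 = 0, s2 = 0, s3 = 0;
  int d = 0;
  for (; d + 4 <= D; d += 4) {
    s0 += w[d] * x[d];
    s1 += w[d + 1] * x[d + 1];
    s2 += w[d + 2] * x[d + 2];
    s3 += w[d + 3] * x[d + 3];
  }
  double z = (s0 + s1) + (s2 + s3);
  for (; d < D; ++d) z += w[d] * x[d];
  return z;
}

// Hidden pre-activation contribution of the (offset-invariant) context
// block; zero when context mode is off.
static inline void ctx_preact(const double* xc, int ctxdim, int D,
                              const std::vector<double>& W1, int h,
                              double* zc) {
  for (int q = 0; q < h; ++q)
    zc[q] = ctxdim ? dot(&W1[(size_t)q * D + BASE_DIM], xc, ctxdim) : 0.0;
}

static inline double fwd_col(const double* xb, const double* zc, int D,
                             const std::vector<double>& W1,
                             const std::vector<double>& b1, const double* w2,
                             double b2, int h, double* hh) {
  double o = b2;
  for (int q = 0; q < h; ++q) {
    hh[q] = sigm(b1[q] + zc[q] + dot(&W1[(size_t)q * D], xb, BASE_DIM));
    o += w2[q] * hh[q];
  }
  return sigm(o);
}

// Balanced mixed-data online training with burn-in restricted core search.
// head: 0 = BA, 1 = EL. use_idx: 0-based instance indices of the training
// subset. All randomness goes through R's RNG (set.seed upstream).
// [[Rcpp::export]]
List cpp_train(NumericMatrix feat, NumericMatrix ctx_feat,
               IntegerVector col_start, IntegerVector n_off,
               LogicalVector p1h, NumericVector target, IntegerVector head,
               IntegerVector use_idx, int n_hidden, int iterations,
               int burn_in, double lr, double init_range) {
  const int ctxdim = ctx_feat.nrow();
  const int D = BASE_DIM + ctxdim;
  const double* F = feat.begin();
  const double* C = ctx_feat.begin();
  const int h = n_hidden;
  if (iterations <= burn_in || burn_in < 0)
    stop("iterations must exceed burn_in_iterations >= 0");
  std::vector<double> W1((size_t)D * h), b1(h), w2(2 * h), b2(2);
  for (size_t i = 0; i < W1.size(); ++i) W1[i] = (unif_rand() * 2 - 1) * init_range;
  for (int q = 0; q < h; ++q) b1[q] = (unif_rand() * 2 - 1) * init_range;
  for (int q = 0; q < 2 * h; ++q) w2[q] = (unif_rand() * 2 - 1) * init_range;
  b2[0] = (unif_rand() * 2 - 1) * init_range;
  b2[1] = (unif_rand() * 2 - 1) * init_range;

  std::vector<int> pool[2];
  for (int s = 0; s < use_idx.size(); ++s) pool[head[use_idx[s]]].push_back(use_idx[s]);
  if (pool[0].empty() && pool[1].empty()) stop("empty training set");
  bool both = !pool[0].empty() && !pool[1].empty();
  int only = pool[0].empty() ? 1 : 0;

  const int n = col_start.size();
  std::vector<char> adm(n, 0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < n_off[i]; ++k)
      if (p1h[col_start[i] + k]) { adm[i] = 1; break; }

  const R_xlen_t nsteps = use_idx.size();
  std::vector<double> hh(h), hbest(h), zc(h);
  double ndraw[2] = {0.0, 0.0};
  for (int it = 0; it < iterations; ++it) {
    bool burn = it < burn_in;
    for (R_xlen_t s = 0; s < nsteps; ++s) {
      int t;
      if (both) t = (unif_rand() < 0.5) ? 0 : 1; else t = only;
      int sz = (int)pool[t].size();
      int j = (int)(unif_rand() * sz);
      if (j >= sz) j = sz - 1;
      int i = pool[t][j];
      ndraw[t] += 1.0;
      const double* xc = ctxdim ? C + (size_t)i * ctxdim : nullptr;
      ctx_preact(xc, ctxdim, D, W1, h, zc.data());
      int best = -1;
      double bestscore = -1.0;
      for (int k = 0; k < n_off[i]; ++k) {
        int col = col_start[i] + k;
        if (burn && adm[i] && !p1h[col]) continue;
        double out = fwd_col(F + (size_t)col * BASE_DIM, zc.data(), D, W1, b1,
                             &w2[t * h], b2[t], h, hh.data());
        if (out > bestscore) { bestscore = out; best = col; hbest = hh; }
      }
      const double* xb = F + (size_t)best * BASE_DIM;
      double out = bestscore;
      double dOut = (out - target[i]) * out * (1.0 - out);
      for (int q = 0; q < h; ++q) {
        double dH = dOut * w2[t * h + q] * hbest[q] * (1.0 - hbest[q]);
        w2[t * h + q] -= lr * dOut * hbest[q];
        double* w = &W1[(size_t)q * D];
        double g = lr * dH;
        for (int d = 0; d < BASE_DIM; ++d) w[d] -= g * xb[d];
        for (int d = 0; d < ctxdim; ++d) w[BASE_DIM + d] -= g * xc[d];
        b1[q] -= lr * dH;
      }
      b2[t] -= lr * dOut;
    }
  }
  NumericMatrix w1(D, h);
  std::copy(W1.begin(), W1.end(), w1.begin());
  return List::create(
      _["w1"] = w1, _["b1"] = NumericVector(b1.begin(), b1.end()),
      _["w2_ba"] = NumericVector(w2.begin(), w2.begin() + h),
      _["b2_ba"] = b2[0],
      _["w2_el"] = NumericVector(w2.begin() + h, w2.end()),
      _["b2_el"] = b2[1],
      _["n_draws"] = NumericVector::create(_["BA"] = ndraw[0], _["EL"] = ndraw[1]));
}

// Max-over-offsets prediction for one head; ties resolved to the smallest
// offset. Returns per-instance best score and 0-based best offset.
// [[Rcpp::export]]
List cpp_predict(NumericMatrix feat, NumericMatrix ctx_feat,
                 IntegerVector col_start, IntegerVector n_off,
                 IntegerVector use_idx, NumericMatrix w1, NumericVector b1,
                 NumericVector w2, double b2) {
  const int ctxdim = ctx_feat.nrow();
  const int D = BASE_DIM + ctxdim;
  if (w1.nrow() != D) stop("feature-length mismatch between model and input");
  const int h = w1.ncol();
  const double* F = feat.begin();
  const double* C = ctx_feat.begin();
  std::vector<double> W1(w1.begin(), w1.end());
  std::vector<double> B1(b1.begin(), b1.end());
  std::vector<double> W2(w2.begin(), w2.end());
  std::vector<double> hh(h), zc(h);
  int m = use_idx.size();
  NumericVector score(m);
  IntegerVector offset(m);
  for (int s = 0; s < m; ++s) {
    int i = use_idx[s];
    const double* xc = ctxdim ? C + (size_t)i * ctxdim : nullptr;
    ctx_preact(xc, ctxdim, D, W1, h, zc.data());
    int best = 0;
    double bestscore = -1.0;
    for (int k = 0; k < n_off[i]; ++k) {
      int col = col_start[i] + k;
      double out = fwd_col(F + (size_t)col * BASE_DIM, zc.data(), D, W1, B1,
                           W2.data(), b2, h, hh.data());
      if (out > bestscore) { bestscore = out; best = k; }
    }
    score[s] = bestscore;
    offset[s] = best;
  }
  return List::create(_["score"] = score, _["offset"] = offset);
}

// Raw per-column network outputs for ONE instance (its context vector may
// be empty when context mode is off). Used by select_core and tests.
// [[Rcpp::export]]
NumericVector cpp_forward_cols(NumericMatrix feat, IntegerVector cols,
                               NumericVector ctx_vec, NumericMatrix w1,
                               NumericVector b1, NumericVector w2,
                               double b2) {
  const int ctxdim = ctx_vec.size();
  const int D = BASE_DIM + ctxdim;
  if (w1.nrow() != D) stop("feature-length mismatch between model and input");
  const int h = w1.ncol();
  std::vector<double> W1(w1.begin(), w1.end());
  std::vector<double> B1(b1.begin(), b1.end());
  std::vector<double> W2(w2.begin(), w2.end());
  std::vector<double> hh(h), zc(h);
  ctx_preact(ctxdim ? ctx_vec.begin() : nullptr, ctxdim, D, W1, h, zc.data());
  NumericVector out(cols.size());
  for (int s = 0; s < cols.size(); ++s)
    out[s] = fwd_col(feat.begin() + (size_t)cols[s] * BASE_DIM, zc.data(), D,
                     W1, B1, W2.data(), b2, h, hh.data());
  return out;
}
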