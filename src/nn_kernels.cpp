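// Fused batched kernels for the dual-branch network's hot paths: the
// bidirectional LSTM recurrence (forward and backpropagation through time)
// and the conv -> ReLU -> max-pool / SE-scale stages of the spatial branch.
//
// Large intermediates (gate activations, cell states, pre-pool maps) never
// cross the R boundary: each forward call returns an external pointer to a
// cache object that the matching backward call consumes.
//
// Layout conventions (column-major, matching R):
//   x          : n x C input batch (each row one sample, feat width 1)
//   position-major matrices ("flat maps"): (n*C) x F with row index
//                i + n*(t-1) for sample i at position t
//   Hcat       : cube n x 2U x C; columns 0..U-1 forward states, U..2U-1
//                backward states, slice t = original position t
//   gate cubes : n x 4U per slice, post-activation [i | f | g | o],
//                stored in processing order of the direction

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

#include <cstring>
#include <cstdint>
#if defined(__GLIBC__)
#include <malloc.h>
#endif

using namespace arma;

// The per-batch cache buffers are tens of MB; with glibc's defaults each
// allocation is a fresh mmap and every release returns the pages to the
// kernel, so the training loop pays soft page faults on every batch. Raising
// the mmap/trim thresholds keeps the blocks on the heap for reuse. Called
// once from .onLoad; a no-op on other allocators.
// [[Rcpp::export]]
void tune_allocator_cpp() {
#if defined(__GLIBC__)
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}

// Branch-free exp for the gate nonlinearities: range reduction
// x = n*ln2 + r with round-to-nearest via the 2^52 magic constant, a
// Cephes-style 2/2 Pade approximant for e^r on [-ln2/2, ln2/2], and
// exponent reconstruction through the IEEE-754 bit layout. Accurate to
// ~1 ulp over the clamped range; pure arithmetic and integer ops, so the
// gate loops auto-vectorize (no libm calls).
static inline double fast_exp(double x) {
  // clamp: beyond these the logistic/tanh outputs saturate anyway
  x = x > 708.0 ? 708.0 : (x < -708.0 ? -708.0 : x);
  const double log2e = 1.4426950408889634073599;
  const double magic = 6755399441055744.0;  // 1.5 * 2^52
  double t = x * log2e + magic;
  double n = t - magic;                     // round(x / ln2)
  // the mantissa of t holds round(x/ln2) as an integer offset from magic
  int64_t tb, mb;
  std::memcpy(&tb, &t, sizeof tb);
  std::memcpy(&mb, &magic, sizeof mb);
  int64_t ni = tb - mb;
  // r = x - n*ln2, ln2 split for extra precision
  double r = x - n * 0.693145751953125;
  r -= n * 1.42860682030941723212e-6;
  // Cephes expd Pade coefficients
  double xx = r * r;
  double px = r * (1.26177193074810590878e-4 * xx * xx +
                   3.02994407707441961300e-2 * xx +
                   9.99999999999999999910e-1);
  double qx = 3.00198505138664455042e-6 * xx * xx * xx +
              2.52448340349684104192e-3 * xx * xx +
              2.27265548208155028766e-1 * xx + 2.0;
  double er = 1.0 + 2.0 * px / (qx - px);
  // scale by 2^n through the exponent bits
  int64_t bits;
  std::memcpy(&bits, &er, sizeof bits);
  bits += ni << 52;
  std::memcpy(&er, &bits, sizeof er);
  return er;
}

static inline double sig(double x) { return 1.0 / (1.0 + fast_exp(-x)); }

static inline double fast_tanh(double x) {
  return 1.0 - 2.0 / (fast_exp(2.0 * x) + 1.0);
}

struct BiLstmCache {
  cube Cf, Gf, Cb, Gb;
};

// One direction's forward sweep over processing order `order`; hidden rows
// are written into Hcat columns [col0, col0+U) at the original positions.
static void lstm_dir_forward(const mat& x, const uvec& order, const mat& W,
                             const rowvec& b, cube& Hcat, uword col0,
                             cube& Cs, cube& G) {
  const uword n = x.n_rows, seq = order.n_elem, U = W.n_cols / 4;
  const mat Wh = W.rows(0, U - 1);
  const rowvec Wx = W.row(U);
  mat h(n, U, fill::zeros), c(n, U, fill::zeros), A(n, 4 * U);
  for (uword s = 0; s < seq; ++s) {
    A = h * Wh;                      // recurrent term, single gemm
    const double* xc = x.colptr(order[s]);
    mat& Gs = G.slice(s);
    mat& Css = Cs.slice(s);
    // input term, bias and activations fused per hidden unit
    for (uword u = 0; u < U; ++u) {
      const double* ai = A.colptr(u);
      const double* af = A.colptr(U + u);
      const double* ag = A.colptr(2 * U + u);
      const double* ao = A.colptr(3 * U + u);
      double* gvi = Gs.colptr(u);
      double* gvf = Gs.colptr(U + u);
      double* gvg = Gs.colptr(2 * U + u);
      double* gvo = Gs.colptr(3 * U + u);
      double* cpu = c.colptr(u);
      double* hpu = h.colptr(u);
      double* csu = Css.colptr(u);
      const double wxi = Wx[u], wxf = Wx[U + u], wxg = Wx[2 * U + u],
                   wxo = Wx[3 * U + u];
      const double bi = b[u], bf = b[U + u], bg = b[2 * U + u],
                   bo = b[3 * U + u];
      for (uword i = 0; i < n; ++i) {
        double gi = sig(ai[i] + xc[i] * wxi + bi);
        double gf = sig(af[i] + xc[i] * wxf + bf);
        double gg = fast_tanh(ag[i] + xc[i] * wxg + bg);
        double go = sig(ao[i] + xc[i] * wxo + bo);
        double cc = gf * cpu[i] + gi * gg;
        cpu[i] = cc;
        csu[i] = cc;
        hpu[i] = go * fast_tanh(cc);
        gvi[i] = gi; gvf[i] = gf; gvg[i] = gg; gvo[i] = go;
      }
    }
    Hcat.slice(order[s]).cols(col0, col0 + U - 1) = h;
  }
}

// [[Rcpp::export]]
Rcpp::List bilstm_forward_cpp(const arma::mat& x, const arma::mat& Wf,
                              const arma::rowvec& bf, const arma::mat& Wb,
                              const arma::rowvec& bb) {
  const uword n = x.n_rows, C = x.n_cols, U = Wf.n_cols / 4;
  if (Wf.n_rows != U + 1 || Wb.n_rows != U + 1)
    Rcpp::stop("bilstm_forward_cpp: gate weights must be (U+1) x 4U");
  cube Hcat(n, 2 * U, C);
  Rcpp::XPtr<BiLstmCache> ptr(new BiLstmCache, true);
  ptr->Cf.set_size(n, U, C); ptr->Gf.set_size(n, 4 * U, C);
  ptr->Cb.set_size(n, U, C); ptr->Gb.set_size(n, 4 * U, C);
  uvec fwd = regspace<uvec>(0, C - 1);
  uvec bwd = reverse(fwd);
  lstm_dir_forward(x, fwd, Wf, bf, Hcat, 0, ptr->Cf, ptr->Gf);
  lstm_dir_forward(x, bwd, Wb, bb, Hcat, U, ptr->Cb, ptr->Gb);
  return Rcpp::List::create(Rcpp::Named("H") = Hcat,
                            Rcpp::Named("cache") = ptr);
}

// One direction's BPTT sweep; accumulates dW and db. dX is not needed (the
// recurrence reads raw inputs), so input gradients are skipped.
static void lstm_dir_backward(const mat& x, const uvec& order, const mat& W,
                              const cube& Hcat, uword col0, const cube& Cs,
                              const cube& G, const cube& dHcat, mat& dW,
                              rowvec& db) {
  const uword n = x.n_rows, seq = order.n_elem, U = W.n_cols / 4;
  const mat WhT = W.rows(0, U - 1).t();
  mat dh(n, U), dc(n, U, fill::zeros), dA(n, 4 * U);
  mat dh_next(n, U, fill::zeros);
  const uword nU = n * U;
  for (uword s = seq; s-- > 0;) {
    dh = dHcat.slice(order[s]).cols(col0, col0 + U - 1) + dh_next;
    const double* g = G.slice(s).memptr();
    const double* cs = Cs.slice(s).memptr();
    const double* csp = (s > 0) ? Cs.slice(s - 1).memptr() : nullptr;
    double* da = dA.memptr();
    const double* dhp = dh.memptr();
    double* dcp = dc.memptr();
    for (uword k = 0; k < nU; ++k) {
      double gi = g[k], gf = g[k + nU], gg = g[k + 2 * nU],
             go = g[k + 3 * nU];
      double tc = fast_tanh(cs[k]);
      double cprev = csp ? csp[k] : 0.0;
      double dgo = dhp[k] * tc;
      double dcc = dcp[k] + dhp[k] * go * (1.0 - tc * tc);
      da[k] = dcc * gg * gi * (1.0 - gi);
      da[k + nU] = dcc * cprev * gf * (1.0 - gf);
      da[k + 2 * nU] = dcc * gi * (1.0 - gg * gg);
      da[k + 3 * nU] = dgo * go * (1.0 - go);
      dcp[k] = dcc * gf;          // becomes dc for step s-1
    }
    if (s > 0) {
      dW.rows(0, U - 1) +=
          Hcat.slice(order[s - 1]).cols(col0, col0 + U - 1).t() * dA;
    }                              // h_0 = 0 contributes nothing
    dW.row(U) += x.col(order[s]).t() * dA;
    db += sum(dA, 0);
    dh_next = dA * WhT;
  }
}

// [[Rcpp::export]]
Rcpp::List bilstm_backward_cpp(SEXP cache, const arma::mat& x,
                               const arma::mat& Wf, const arma::mat& Wb,
                               const arma::cube& Hcat,
                               const arma::cube& dHcat) {
  Rcpp::XPtr<BiLstmCache> ptr(cache);
  const uword C = x.n_cols, U = Wf.n_cols / 4;
  mat dWf(size(Wf), fill::zeros), dWb(size(Wb), fill::zeros);
  rowvec dbf(4 * U, fill::zeros), dbb(4 * U, fill::zeros);
  uvec fwd = regspace<uvec>(0, C - 1);
  uvec bwd = reverse(fwd);
  lstm_dir_backward(x, fwd, Wf, Hcat, 0, ptr->Cf, ptr->Gf, dHcat, dWf, dbf);
  lstm_dir_backward(x, bwd, Wb, Hcat, U, ptr->Cb, ptr->Gb, dHcat, dWb, dbb);
  return Rcpp::List::create(Rcpp::Named("dWf") = dWf, Rcpp::Named("dbf") = dbf,
                            Rcpp::Named("dWb") = dWb,
                            Rcpp::Named("dbb") = dbb);
}

// Eagerly return a cache's buffers to the heap free list (R finalizes the
// external pointer lazily at GC time; with the tuned allocator an eager
// release lets the very next forward call reuse the same blocks instead of
// faulting in fresh pages). The cache must not be used again afterwards.
// [[Rcpp::export]]
void release_bilstm_cache_cpp(SEXP cache) {
  Rcpp::XPtr<BiLstmCache> ptr(cache);
  ptr->Cf.reset(); ptr->Gf.reset(); ptr->Cb.reset(); ptr->Gb.reset();
}

struct SpatialCache {
  mat A;          // (n*C) x F post-ReLU conv maps
  Mat<int> amax;  // (n*wp) x F winning window slot (1-based)
  mat P;          // (n*wp) x F pooled maps
  mat dP;         // gradient buffer filled by the backward chain
};

// Shifted-window design matrix for kernel-size-ksz same-padded conv on a
// width-1 feature sequence: column k holds x shifted by (k - lpad).
static mat conv_unfold(const mat& x, uword ksz) {
  const uword n = x.n_rows, C = x.n_cols, lpad = (ksz - 1) / 2;
  mat M(n * C, ksz, fill::zeros);
  for (uword k = 0; k < ksz; ++k) {
    const sword d = static_cast<sword>(k) - static_cast<sword>(lpad);
    for (sword t = 0; t < static_cast<sword>(C); ++t) {
      sword srct = t + d;
      if (srct >= 0 && srct < static_cast<sword>(C))
        M.submat(t * n, k, (t + 1) * n - 1, k) = x.col(srct);
    }
  }
  return M;
}

// conv -> ReLU -> max pool -> SE squeeze; returns the squeeze vector z and
// the cache pointer for the rest of the spatial branch.
// [[Rcpp::export]]
Rcpp::List conv_pool_fwd_cpp(const arma::mat& x, const arma::mat& Wmat,
                             const arma::rowvec& b, int pool) {
  const uword n = x.n_rows, C = x.n_cols, ksz = Wmat.n_rows,
              F = Wmat.n_cols;
  const uword wp = C / pool;
  Rcpp::XPtr<SpatialCache> ptr(new SpatialCache, true);
  ptr->A = conv_unfold(x, ksz) * Wmat;
  ptr->A.each_row() += b;
  ptr->A.transform([](double v) { return v > 0.0 ? v : 0.0; });  // ReLU
  ptr->P.set_size(n * wp, F);
  ptr->amax.set_size(n * wp, F);
  mat z(n, F, fill::zeros);
  for (uword f = 0; f < F; ++f) {
    const double* a = ptr->A.colptr(f);
    double* p = ptr->P.colptr(f);
    int* am = ptr->amax.colptr(f);
    double* zv = z.colptr(f);
    for (uword t = 0; t < wp; ++t) {
      const uword src0 = n * (t * pool);
      const uword dst0 = n * t;
      for (uword i = 0; i < n; ++i) {
        double best = a[src0 + i];
        int bk = 1;
        for (int k = 1; k < pool; ++k) {
          double v = a[src0 + k * n + i];
          if (v > best) { best = v; bk = k + 1; }   // first max wins ties
        }
        p[dst0 + i] = best;
        am[dst0 + i] = bk;
        zv[i] += best;
      }
    }
  }
  z /= static_cast<double>(wp);
  return Rcpp::List::create(Rcpp::Named("z") = z, Rcpp::Named("cache") = ptr);
}

// out[i + n*t, f] = P[i + n*t, f] * s[i, f]
// [[Rcpp::export]]
arma::mat se_scale_fwd_cpp(SEXP cache, const arma::mat& s) {
  Rcpp::XPtr<SpatialCache> ptr(cache);
  const uword n = s.n_rows, F = s.n_cols, wp = ptr->P.n_rows / n;
  mat out(n * wp, F);
  for (uword f = 0; f < F; ++f) {
    const double* p = ptr->P.colptr(f);
    const double* sv = s.colptr(f);
    double* o = out.colptr(f);
    for (uword t = 0; t < wp; ++t)
      for (uword i = 0; i < n; ++i) o[t * n + i] = p[t * n + i] * sv[i];
  }
  return out;
}

// Gradient of the scale stage: stores dP in the cache for the following
// squeeze/unpool steps and returns ds (n x F).
// [[Rcpp::export]]
arma::mat se_scale_bwd_cpp(SEXP cache, const arma::mat& dout,
                           const arma::mat& s) {
  Rcpp::XPtr<SpatialCache> ptr(cache);
  const uword n = s.n_rows, F = s.n_cols, wp = ptr->P.n_rows / n;
  ptr->dP.set_size(n * wp, F);
  mat ds(n, F, fill::zeros);
  for (uword f = 0; f < F; ++f) {
    const double* d = dout.colptr(f);
    const double* p = ptr->P.colptr(f);
    const double* sv = s.colptr(f);
    double* dpv = ptr->dP.colptr(f);
    double* dsv = ds.colptr(f);
    for (uword t = 0; t < wp; ++t)
      for (uword i = 0; i < n; ++i) {
        dpv[t * n + i] = d[t * n + i] * sv[i];
        dsv[i] += d[t * n + i] * p[t * n + i];
      }
  }
  return ds;
}

// Add the squeeze gradient dz/wp into the cached dP.
// [[Rcpp::export]]
void squeeze_bwd_add_cpp(SEXP cache, const arma::mat& dz) {
  Rcpp::XPtr<SpatialCache> ptr(cache);
  const uword n = dz.n_rows, F = dz.n_cols, wp = ptr->dP.n_rows / n;
  for (uword f = 0; f < F; ++f) {
    const double* d = dz.colptr(f);
    double* dpv = ptr->dP.colptr(f);
    for (uword t = 0; t < wp; ++t)
      for (uword i = 0; i < n; ++i) dpv[t * n + i] += d[i] / wp;
  }
}

// Unpool the cached dP through the ReLU mask and return conv weight/bias
// gradients.
// [[Rcpp::export]]
Rcpp::List conv_pool_bwd_cpp(SEXP cache, const arma::mat& x, int pool,
                             int ksz) {
  Rcpp::XPtr<SpatialCache> ptr(cache);
  const uword n = x.n_rows, C = x.n_cols, F = ptr->A.n_cols;
  const uword wp = ptr->amax.n_rows / n;
  mat dA(n * C, F, fill::zeros);
  for (uword f = 0; f < F; ++f) {
    const double* a = ptr->A.colptr(f);
    const double* dp = ptr->dP.colptr(f);
    const int* am = ptr->amax.colptr(f);
    double* da = dA.colptr(f);
    for (uword t = 0; t < wp; ++t) {
      const uword src0 = n * (t * pool);
      const uword dst0 = n * t;
      for (uword i = 0; i < n; ++i) {
        const uword j = src0 + (am[dst0 + i] - 1) * n + i;
        if (a[j] > 0.0) da[j] += dp[dst0 + i];      // ReLU mask
      }
    }
  }
  mat dWmat = conv_unfold(x, ksz).t() * dA;
  rowvec db = sum(dA, 0);
  return Rcpp::List::create(Rcpp::Named("dW") = dWmat, Rcpp::Named("db") = db);
}

// See release_bilstm_cache_cpp.
// [[Rcpp::export]]
void release_spatial_cache_cpp(SEXP cache) {
  Rcpp::XPtr<SpatialCache> ptr(cache);
  ptr->A.reset(); ptr->amax.reset(); ptr->P.reset(); ptr->dP.reset();
}
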