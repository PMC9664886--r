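// Numeric kernels: im2col convolution (forward/backward), fused Adam and
// leaky-ReLU for the conditional GAN, and lookup-table helpers for the
// SSOP reflectance inversion.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Nearest node (1-based, column-major) in (dc, ac) reflectance space for
// each query pair. Inputs are pre-scaled so the two axes are comparable.
// [[Rcpp::export]]
IntegerVector find_nearest_node(const arma::mat& dc, const arma::mat& ac,
                                const arma::vec& qdc, const arma::vec& qac) {
  const arma::uword n = dc.n_elem, nq = qdc.n_elem;
  IntegerVector out(nq);
  const double* pdc = dc.memptr();
  const double* pac = ac.memptr();
  for (arma::uword q = 0; q < nq; ++q) {
    double best = arma::datum::inf;
    arma::uword bi = 0;
    const double a = qdc(q), b = qac(q);
    for (arma::uword i = 0; i < n; ++i) {
      const double d1 = pdc[i] - a, d2 = pac[i] - b;
      const double d = d1 * d1 + d2 * d2;
      if (d < best) { best = d; bi = i; }
    }
    out[q] = static_cast<int>(bi) + 1;
  }
  return out;
}

// Newton solve of the bilinear patch of one cell (anchor i, j; 0-based)
// from a given start; returns local coords and residual.
static inline void newton_cell(const arma::mat& dc, const arma::mat& ac,
                               int i, int j, double qdc, double qac,
                               double ta0, double ts0,
                               double& ta, double& ts, double& resid) {
  const double f00 = dc(i, j), f10 = dc(i + 1, j), f01 = dc(i, j + 1),
               f11 = dc(i + 1, j + 1);
  const double g00 = ac(i, j), g10 = ac(i + 1, j), g01 = ac(i, j + 1),
               g11 = ac(i + 1, j + 1);
  ta = ta0; ts = ts0;
  double r1 = 0.0, r2 = 0.0;
  for (int it = 0; it < 30; ++it) {
    const double f = f00 * (1 - ta) * (1 - ts) + f10 * ta * (1 - ts) +
                     f01 * (1 - ta) * ts + f11 * ta * ts;
    const double g = g00 * (1 - ta) * (1 - ts) + g10 * ta * (1 - ts) +
                     g01 * (1 - ta) * ts + g11 * ta * ts;
    r1 = f - qdc;
    r2 = g - qac;
    if (std::abs(r1) + std::abs(r2) < 1e-15) break;
    const double dfa = (f10 - f00) * (1 - ts) + (f11 - f01) * ts;
    const double dfs = (f01 - f00) * (1 - ta) + (f11 - f10) * ta;
    const double dga = (g10 - g00) * (1 - ts) + (g11 - g01) * ts;
    const double dgs = (g01 - g00) * (1 - ta) + (g11 - g10) * ta;
    const double det = dfa * dgs - dfs * dga;
    if (std::abs(det) < 1e-300) break;
    double sa = (r1 * dgs - r2 * dfs) / det;
    double ss = (dfa * r2 - dga * r1) / det;
    const double lim = 1.0;
    if (std::abs(sa) > lim) sa = (sa > 0 ? lim : -lim);
    if (std::abs(ss) > lim) ss = (ss > 0 ? lim : -lim);
    ta -= sa;
    ts -= ss;
    if (ta < -0.5) ta = -0.5; if (ta > 1.5) ta = 1.5;
    if (ts < -0.5) ts = -0.5; if (ts > 1.5) ts = 1.5;
  }
  resid = std::sqrt(r1 * r1 + r2 * r2);
}

// Invert the tabulated (rd_dc, rd_ac) -> (mu_a, mu_s') map around the
// nearest node (1-based indices ia_node, is_node): multi-start Newton over
// the up-to-4 surrounding cells; the lowest-residual solution wins, with a
// tie-break toward the solution closest to the node (the bilinear patch is
// near-degenerate at low albedo where multiple pre-images exist). Returns
// nq x 3: fractional grid coordinates (1-based) along each axis and the
// residual.
// [[Rcpp::export]]
NumericMatrix invert_bilinear_cells(const arma::mat& dc, const arma::mat& ac,
                                    const IntegerVector& ia_node,
                                    const IntegerVector& is_node,
                                    const arma::vec& qdc,
                                    const arma::vec& qac) {
  const int na = dc.n_rows, ns = dc.n_cols;
  const int nq = qdc.n_elem;
  NumericMatrix out(nq, 3);
  const double starts[5][2] = {{0.5, 0.5}, {0.0, 0.0}, {1.0, 0.0},
                               {0.0, 1.0}, {1.0, 1.0}};
  for (int q = 0; q < nq; ++q) {
    const int in_a = ia_node[q] - 1, in_s = is_node[q] - 1;
    double best_resid = arma::datum::inf, best_a = in_a, best_s = in_s,
           best_d = arma::datum::inf;
    for (int ca = in_a - 1; ca <= in_a; ++ca) {
      if (ca < 0 || ca > na - 2) continue;
      for (int cs = in_s - 1; cs <= in_s; ++cs) {
        if (cs < 0 || cs > ns - 2) continue;
        for (int s = 0; s < 5; ++s) {
          double ta, ts, resid;
          newton_cell(dc, ac, ca, cs, qdc(q), qac(q),
                      starts[s][0], starts[s][1], ta, ts, resid);
          const double ga = ca + ta, gs = cs + ts;
          const double d = (ga - in_a) * (ga - in_a) +
                           (gs - in_s) * (gs - in_s);
          if (resid < best_resid - 1e-14 ||
              (resid < best_resid + 1e-14 && d < best_d)) {
            best_resid = std::min(resid, best_resid);
            best_a = ga; best_s = gs; best_d = d;
          }
        }
      }
    }
    out(q, 0) = best_a + 1.0;  // back to 1-based fractional grid coords
    out(q, 1) = best_s + 1.0;
    out(q, 2) = best_resid;
  }
  return out;
}

// ---- convolution -----------------------------------------------------------
// Weights are R arrays of dim (kh, kw, cin, cout); their column-major
// flattening is exactly the (K x Cout) matrix with K = kh*kw*cin ordered
// (kr, kc, c), so matrices are zero-copy views onto the R data.

// Transposed im2col: Mt is (Hout*Wout) x K; for stride 1 the inner copy is
// contiguous in both source and destination.
static void im2col_t(const arma::cube& x, int kh, int kw, int stride,
                     int pad, int Hout, int Wout, arma::mat& Mt) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  Mt.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xs = x.slice(c).memptr();
    for (int kc = 0; kc < kw; ++kc) {
      for (int kr = 0; kr < kh; ++kr) {
        double* dst = Mt.colptr(kr + kh * (kc + kw * c));
        for (int wo = 0; wo < Wout; ++wo) {
          const int wi = wo * stride + kc - pad;
          if (wi < 0 || wi >= W) continue;
          const double* src = xs + static_cast<size_t>(wi) * H;
          double* d = dst + static_cast<size_t>(wo) * Hout;
          if (stride == 1) {
            int ho0 = std::max(0, pad - kr);
            int ho1 = std::min(Hout, H + pad - kr);
            if (ho1 > ho0)
              std::memcpy(d + ho0, src + ho0 + kr - pad,
                          sizeof(double) * (ho1 - ho0));
          } else {
            for (int ho = 0; ho < Hout; ++ho) {
              const int hi = ho * stride + kr - pad;
              if (hi >= 0 && hi < H) d[ho] = src[hi];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward(const arma::cube& x, const NumericVector& w,
                             const arma::vec& b, int stride, int pad) {
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int H = x.n_rows, W = x.n_cols;
  const int Hout = (H + 2 * pad - kh) / stride + 1;
  const int Wout = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * Cin;
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat Mt(Hout * Wout, K);
  im2col_t(x, kh, kw, stride, pad, Hout, Wout, Mt);
  NumericVector out(Hout * Wout * Cout);
  out.attr("dim") = IntegerVector::create(Hout, Wout, Cout);
  arma::mat Y(out.begin(), Hout * Wout, Cout, false, true);
  Y = Mt * Wm;
  Y.each_row() += b.t();
  return out;
}

// [[Rcpp::export]]
List conv2d_backward(const arma::cube& x, const NumericVector& w,
                     const arma::cube& dy, int stride, int pad) {
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int H = x.n_rows, W = x.n_cols;
  const int Hout = dy.n_rows, Wout = dy.n_cols;
  const int K = kh * kw * Cin;
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  const arma::mat Dmt(const_cast<double*>(dy.memptr()), Hout * Wout, Cout,
                      false, true);
  arma::mat Mt(Hout * Wout, K);
  im2col_t(x, kh, kw, stride, pad, Hout, Wout, Mt);
  NumericVector dwv(K * Cout);
  dwv.attr("dim") = wd;
  arma::mat dW(dwv.begin(), K, Cout, false, true);
  dW = Mt.t() * Dmt;
  arma::vec db = arma::sum(Dmt, 0).t();
  arma::mat dMt = Dmt * Wm.t();  // (Hout*Wout) x K
  // col2im accumulation
  arma::cube dx(H, W, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    double* xs = dx.slice(c).memptr();
    for (int kc = 0; kc < kw; ++kc) {
      for (int kr = 0; kr < kh; ++kr) {
        const double* src0 = dMt.colptr(kr + kh * (kc + kw * c));
        for (int wo = 0; wo < Wout; ++wo) {
          const int wi = wo * stride + kc - pad;
          if (wi < 0 || wi >= W) continue;
          double* d = xs + static_cast<size_t>(wi) * H;
          const double* s = src0 + static_cast<size_t>(wo) * Hout;
          for (int ho = 0; ho < Hout; ++ho) {
            const int hi = ho * stride + kr - pad;
            if (hi >= 0 && hi < H) d[hi] += s[ho];
          }
        }
      }
    }
  }
  return List::create(Named("dx") = dx, Named("dw") = dwv,
                      Named("db") = db);
}

// ---- fused optimiser / activation kernels ---------------------------------

// One Adam step; returns updated (w, m, v) in a single fused pass.
// [[Rcpp::export]]
List adam_update(const NumericVector& w, const NumericVector& g,
                 const NumericVector& m, const NumericVector& v,
                 double lr, double beta1, double beta2, double eps, int t) {
  const R_xlen_t n = w.size();
  NumericVector w2(n), m2(n), v2(n);
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  const double* pw = w.begin(); const double* pg = g.begin();
  const double* pm = m.begin(); const double* pv = v.begin();
  double* qw = w2.begin(); double* qm = m2.begin(); double* qv = v2.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double mi = beta1 * pm[i] + (1 - beta1) * pg[i];
    const double vi = beta2 * pv[i] + (1 - beta2) * pg[i] * pg[i];
    qm[i] = mi; qv[i] = vi;
    qw[i] = pw[i] - lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
  if (w.hasAttribute("dim")) {
    w2.attr("dim") = w.attr("dim");
    m2.attr("dim") = w.attr("dim");
    v2.attr("dim") = w.attr("dim");
  }
  return List::create(Named("w") = w2, Named("m") = m2, Named("v") = v2);
}

// [[Rcpp::export]]
NumericVector lrelu_fwd(const NumericVector& x, double slope) {
  const R_xlen_t n = x.size();
  NumericVector y(n);
  const double* px = x.begin(); double* py = y.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    py[i] = px[i] > 0 ? px[i] : slope * px[i];
  }
  if (x.hasAttribute("dim")) y.attr("dim") = x.attr("dim");
  return y;
}

// Backward pass inferred from the forward output (sign is preserved).
// [[Rcpp::export]]
NumericVector lrelu_bwd(const NumericVector& y, const NumericVector& dy,
                        double slope) {
  const R_xlen_t n = y.size();
  NumericVector dx(n);
  const double* py = y.begin(); const double* pd = dy.begin();
  double* px = dx.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    px[i] = py[i] > 0 ? pd[i] : slope * pd[i];
  }
  if (dy.hasAttribute("dim")) dx.attr("dim") = dy.attr("dim");
  return dx;
}
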