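// Batched matrix multiplication kernels for the autodiff tape.
//
// R arrays (n, p, q) are column-major with the batch index fastest; the
// kernels index that layout directly so no permutation is needed on the R
// side.

#include <Rcpp.h>
using namespace Rcpp;

// out(i,,) = A(i,,) %*% B(i,,)   A: (n,p,q), B: (n,q,r) -> (n,p,r)
// [[Rcpp::export]]
NumericVector bmm_fwd(NumericVector A, NumericVector B,
                      int n, int p, int q, int r) {
  NumericVector out(static_cast<R_xlen_t>(n) * p * r);
  const double* a = A.begin();
  const double* b = B.begin();
  double* o = out.begin();
  for (int c = 0; c < r; ++c)
    for (int k = 0; k < q; ++k)
      for (int rw = 0; rw < p; ++rw) {
        const double* ak = a + static_cast<R_xlen_t>(n) * (rw + static_cast<R_xlen_t>(p) * k);
        const double* bk = b + static_cast<R_xlen_t>(n) * (k + static_cast<R_xlen_t>(q) * c);
        double* ok = o + static_cast<R_xlen_t>(n) * (rw + static_cast<R_xlen_t>(p) * c);
        for (int i = 0; i < n; ++i) ok[i] += ak[i] * bk[i];
      }
  out.attr("dim") = IntegerVector::create(n, p, r);
  return out;
}

// gA(i,,) = G(i,,) %*% t(B(i,,))   G: (n,p,r), B: (n,q,r) -> (n,p,q)
// [[Rcpp::export]]
NumericVector bmm_grad_a(NumericVector G, NumericVector B,
                         int n, int p, int q, int r) {
  NumericVector out(static_cast<R_xlen_t>(n) * p * q);
  const double* g = G.begin();
  const double* b = B.begin();
  double* o = out.begin();
  for (int k = 0; k < q; ++k)
    for (int c = 0; c < r; ++c)
      for (int rw = 0; rw < p; ++rw) {
        const double* gk = g + static_cast<R_xlen_t>(n) * (rw + static_cast<R_xlen_t>(p) * c);
        const double* bk = b + static_cast<R_xlen_t>(n) * (k + static_cast<R_xlen_t>(q) * c);
        double* ok = o + static_cast<R_xlen_t>(n) * (rw + static_cast<R_xlen_t>(p) * k);
        for (int i = 0; i < n; ++i) ok[i] += gk[i] * bk[i];
      }
  out.attr("dim") = IntegerVector::create(n, p, q);
  return out;
}

// gB(i,,) = t(A(i,,)) %*% G(i,,)   A: (n,p,q), G: (n,p,r) -> (n,q,r)
// [[Rcpp::export]]
NumericVector bmm_grad_b(NumericVector A, NumericVector G,
                         int n, int p, int q, int r) {
  NumericVector out(static_cast<R_xlen_t>(n) * q * r);
  const double* a = A.begin();
  const double* g = G.begin();
  double* o = out.begin();
  for (int c = 0; c < r; ++c)
    for (int k = 0; k < q; ++k)
      for (int rw = 0; rw < p; ++rw) {
        const double* ak = a + static_cast<R_xlen_t>(n) * (rw + static_cast<R_xlen_t>(p) * k);
        const double* gk = g + static_cast<R_xlen_t>(n) * (rw + static_cast<R_xlen_t>(p) * c);
        double* ok = o + static_cast<R_xlen_t>(n) * (k + static_cast<R_xlen_t>(q) * c);
        for (int i = 0; i < n; ++i) ok[i] += ak[i] * gk[i];
      }
  out.attr("dim") = IntegerVector::create(n, q, r);
  return out;
}

// fused exact GELU: y = x * Phi(x); also returns Phi(x) for the backward
// [[Rcpp::export]]
List gelu_fwd(NumericVector x) {
  R_xlen_t n = x.size();
  NumericVector y(n), ph(n);
  const double isq2 = 0.7071067811865475;
  for (R_xlen_t i = 0; i < n; ++i) {
    double p = 0.5 * erfc(-x[i] * isq2);
    ph[i] = p;
    y[i] = x[i] * p;
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["ph"] = ph);
}

// GELU backward: g * (Phi(x) + x * phi(x))
// [[Rcpp::export]]
NumericVector gelu_bwd(NumericVector g, NumericVector x, NumericVector ph) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  const double inv_sqrt2pi = 0.3989422804014327;
  for (R_xlen_t i = 0; i < n; ++i) {
    double d = inv_sqrt2pi * exp(-0.5 * x[i] * x[i]);
    out[i] = g[i] * (ph[i] + x[i] * d);
  }
  out.attr("dim") = g.attr("dim");
  return out;
}

// fused ADAM update: m and v are updated in place (they are owned solely by
// the optimizer state); returns the new parameter array
// [[Rcpp::export]]
NumericVector adam_update(NumericVector p, NumericVector m, NumericVector v,
                          NumericVector g, double lr, double b1, double b2,
                          double eps, double b1t, double b2t) {
  R_xlen_t n = p.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double mi = b1 * m[i] + (1 - b1) * g[i];
    double vi = b2 * v[i] + (1 - b2) * g[i] * g[i];
    m[i] = mi; v[i] = vi;
    out[i] = p[i] - lr * (mi / b1t) / (sqrt(vi / b2t) + eps);
  }
  out.attr("dim") = p.attr("dim");
  return out;
}

// fused window partition: (B,H,W,C) -> (B*nh*nw, w*w, C), batch fastest in
// the window axis, row-fastest tokens (matches the reshape/permute chain)
// [[Rcpp::export]]
NumericVector win_part_fwd(NumericVector x, int B, int H, int W, int C, int w) {
  int nh = H / w, nw = W / w;
  R_xlen_t NW = static_cast<R_xlen_t>(B) * nh * nw, T = static_cast<R_xlen_t>(w) * w;
  NumericVector out(NW * T * C);
  double* o = out.begin();
  const double* xp = x.begin();
  R_xlen_t oi = 0;
  for (int c = 0; c < C; ++c)
    for (int wi = 0; wi < w; ++wi)
      for (int hi = 0; hi < w; ++hi)
        for (int wb = 0; wb < nw; ++wb)
          for (int hb = 0; hb < nh; ++hb) {
            R_xlen_t base = static_cast<R_xlen_t>(B) *
              ((hi + hb * w) + static_cast<R_xlen_t>(H) *
               ((wi + wb * w) + static_cast<R_xlen_t>(W) * c));
            for (int b = 0; b < B; ++b) o[oi++] = xp[b + base];
          }
  out.attr("dim") = IntegerVector::create(NW, T, C);
  return out;
}

// inverse scatter of win_part_fwd
// [[Rcpp::export]]
NumericVector win_part_bwd(NumericVector g, int B, int H, int W, int C, int w) {
  int nh = H / w, nw = W / w;
  NumericVector out(static_cast<R_xlen_t>(B) * H * W * C);
  double* o = out.begin();
  const double* gp = g.begin();
  R_xlen_t gi = 0;
  for (int c = 0; c < C; ++c)
    for (int wi = 0; wi < w; ++wi)
      for (int hi = 0; hi < w; ++hi)
        for (int wb = 0; wb < nw; ++wb)
          for (int hb = 0; hb < nh; ++hb) {
            R_xlen_t base = static_cast<R_xlen_t>(B) *
              ((hi + hb * w) + static_cast<R_xlen_t>(H) *
               ((wi + wb * w) + static_cast<R_xlen_t>(W) * c));
            for (int b = 0; b < B; ++b) o[b + base] = gp[gi++];
          }
  out.attr("dim") = IntegerVector::create(B, H, W, C);
  return out;
}

// fused space-to-depth: (B,H,W,C) -> (B,H/p,W/p,p*p*C); folded channel
// order is (row offset fastest, then column offset, then source channel)
// [[Rcpp::export]]
NumericVector s2d_fwd(NumericVector x, int B, int H, int W, int C, int p) {
  int nh = H / p, nw = W / p;
  NumericVector out(static_cast<R_xlen_t>(B) * H * W * C);
  double* o = out.begin();
  const double* xp = x.begin();
  R_xlen_t oi = 0;
  for (int c = 0; c < C; ++c)
    for (int wi = 0; wi < p; ++wi)
      for (int hi = 0; hi < p; ++hi)
        for (int wb = 0; wb < nw; ++wb)
          for (int hb = 0; hb < nh; ++hb) {
            R_xlen_t base = static_cast<R_xlen_t>(B) *
              ((hi + hb * p) + static_cast<R_xlen_t>(H) *
               ((wi + wb * p) + static_cast<R_xlen_t>(W) * c));
            for (int b = 0; b < B; ++b) o[oi++] = xp[b + base];
          }
  out.attr("dim") = IntegerVector::create(B, nh, nw, p * p * C);
  return out;
}

// inverse scatter of s2d_fwd (equivalently: pixel-shuffle forward)
// [[Rcpp::export]]
NumericVector s2d_bwd(NumericVector g, int B, int H, int W, int C, int p) {
  int nh = H / p, nw = W / p;
  NumericVector out(static_cast<R_xlen_t>(B) * H * W * C);
  double* o = out.begin();
  const double* gp = g.begin();
  R_xlen_t gi = 0;
  for (int c = 0; c < C; ++c)
    for (int wi = 0; wi < p; ++wi)
      for (int hi = 0; hi < p; ++hi)
        for (int wb = 0; wb < nw; ++wb)
          for (int hb = 0; hb < nh; ++hb) {
            R_xlen_t base = static_cast<R_xlen_t>(B) *
              ((hi + hb * p) + static_cast<R_xlen_t>(H) *
               ((wi + wb * p) + static_cast<R_xlen_t>(W) * c));
            for (int b = 0; b < B; ++b) o[b + base] = gp[gi++];
          }
  out.attr("dim") = IntegerVector::create(B, H, W, C);
  return out;
}
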