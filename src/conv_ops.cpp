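// 3x3 same-padding convolution on (B*H*W x C) stacked feature matrices,
// computed as nine shifted BLAS GEMMs over a zero-padded plane.  Each batch
// member is padded separately; a kernel offset (di, dj) is then a constant
// shift of the padded linear index, so no im2col matrix is ever formed.

#include <Rcpp.h>
#include <R_ext/BLAS.h>
using namespace Rcpp;

static inline void dgemm_shift(const double* A, int lda, const double* Bm, int ldb,
                               double* C, int ldc, int M, int K, int N,
                               double alpha, double beta, char ta) {
  const char* tA = &ta;
  const char nb = 'N';
  F77_CALL(dgemm)(tA, &nb, &M, &N, &K, &alpha, A, &lda, Bm, &ldb, &beta,
                  C, &ldc FCONE FCONE);
}

// Scatter interior rows of a (B*H*W x C) matrix into zero-padded planes
// ((H+2)(W+2) per member), returning a (B*npad1 x C) matrix.
static std::vector<double> to_padded(const NumericMatrix& x, int H, int W, int B) {
  const int npx = H * W, npad1 = (H + 2) * (W + 2);
  const int C = x.ncol();
  std::vector<double> xp((size_t)B * npad1 * C, 0.0);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, 0) + (size_t)c * B * npx;
    double* xpc = xp.data() + (size_t)c * B * npad1;
    for (int b = 0; b < B; ++b) {
      const double* src = xc + (size_t)b * npx;
      double* dst = xpc + (size_t)b * npad1;
      for (int j = 0; j < W; ++j) {
        // interior of padded column j+1 starts at (j+1)*(H+2) + 1
        std::copy(src + (size_t)j * H, src + (size_t)(j + 1) * H,
                  dst + (size_t)(j + 1) * (H + 2) + 1);
      }
    }
  }
  return xp;
}

// Gather interior rows of padded planes back into a (B*H*W x C) matrix.
static void from_padded(const double* xp, NumericMatrix& out, int H, int W, int B) {
  const int npx = H * W, npad1 = (H + 2) * (W + 2);
  const int C = out.ncol();
  for (int c = 0; c < C; ++c) {
    double* oc = &out(0, 0) + (size_t)c * B * npx;
    const double* xpc = xp + (size_t)c * B * npad1;
    for (int b = 0; b < B; ++b) {
      double* dst = oc + (size_t)b * npx;
      const double* src = xpc + (size_t)b * npad1;
      for (int j = 0; j < W; ++j)
        std::copy(src + (size_t)(j + 1) * (H + 2) + 1,
                  src + (size_t)(j + 1) * (H + 2) + 1 + H,
                  dst + (size_t)j * H);
    }
  }
}

// W is (9*Cin x Cout), kernel offsets ordered di fastest (di, dj in -1..1),
// matching row blocks of size Cin per offset.
// [[Rcpp::export]]
List conv3x3_fwd_cpp(const NumericMatrix& x, const NumericMatrix& Wm,
                     const NumericVector& bias, int H, int W, int B,
                     bool relu = false) {
  const int npx = H * W, npad1 = (H + 2) * (W + 2);
  const int npad = B * npad1;
  const int Cin = x.ncol(), Cout = Wm.ncol();
  std::vector<double> xp = to_padded(x, H, W, B);
  std::vector<double> outp((size_t)npad * Cout, 0.0);
  int k = 0;
  for (int dj = -1; dj <= 1; ++dj) for (int di = -1; di <= 1; ++di, ++k) {
    const int s = dj * (H + 2) + di;
    const double* A = xp.data() + (s > 0 ? s : 0);
    double* Cm = outp.data() + (s < 0 ? -s : 0);
    const int M = npad - (s > 0 ? s : -s);
    dgemm_shift(A, npad, &Wm(0, 0) + k * Cin, 9 * Cin > 0 ? Wm.nrow() : 1,
                Cm, npad, M, Cin, Cout, 1.0, 1.0, 'N');
  }
  NumericMatrix out(B * npx, Cout);
  from_padded(outp.data(), out, H, W, B);
  for (int c = 0; c < Cout; ++c) {
    double* oc = &out(0, 0) + (size_t)c * B * npx;
    const double bc = bias[c];
    if (relu) {
      for (int p = 0; p < B * npx; ++p) {
        const double v = oc[p] + bc;
        oc[p] = v > 0.0 ? v : 0.0;
      }
    } else {
      for (int p = 0; p < B * npx; ++p) oc[p] += bc;
    }
  }
  // keep the padded input for the backward pass
  NumericVector xpv((R_xlen_t)xp.size());
  std::copy(xp.begin(), xp.end(), xpv.begin());
  return List::create(_["out"] = out, _["xp"] = xpv);
}

// [[Rcpp::export]]
List conv3x3_bwd_cpp(const NumericMatrix& dout, const NumericVector& xpv,
                     const NumericMatrix& Wm, int H, int W, int B,
                     bool want_dx, Nullable<NumericMatrix> act = R_NilValue) {
  const int npx = H * W, npad1 = (H + 2) * (W + 2);
  const int npad = B * npad1;
  const int Cout = dout.ncol();
  const int Cin = Wm.nrow() / 9;
  // mask by the ReLU derivative of this layer's activation, if given
  NumericMatrix dz = dout;
  if (act.isNotNull()) {
    NumericMatrix a(act);
    dz = NumericMatrix(dout.nrow(), Cout);
    const double* ap = &a(0, 0);
    const double* dp = &dout(0, 0);
    double* zp = &dz(0, 0);
    const size_t n = (size_t)dout.nrow() * Cout;
    for (size_t p = 0; p < n; ++p) zp[p] = ap[p] > 0.0 ? dp[p] : 0.0;
  }
  // pad the upstream gradient
  std::vector<double> dop = to_padded(dz, H, W, B);
  const double* xp = xpv.begin();

  NumericMatrix dW(9 * Cin, Cout);
  int k = 0;
  for (int dj = -1; dj <= 1; ++dj) for (int di = -1; di <= 1; ++di, ++k) {
    const int s = dj * (H + 2) + di;
    // dW_k = shift(xp)^T %*% dout_pad over the overlapping row range
    const double* A = xp + (s > 0 ? s : 0);
    const double* Dm = dop.data() + (s < 0 ? -s : 0);
    const int M = npad - (s > 0 ? s : -s);
    // (Cin x M) * (M x Cout): use dgemm with transA = 'T'
    dgemm_shift(A, npad, Dm, npad, &dW(0, 0) + k * Cin, 9 * Cin,
                Cin, M, Cout, 1.0, 0.0, 'T');
  }
  NumericVector db(Cout);
  for (int c = 0; c < Cout; ++c) {
    const double* dc = &dz(0, 0) + (size_t)c * B * npx;
    double acc = 0.0;
    for (int p = 0; p < B * npx; ++p) acc += dc[p];
    db[c] = acc;
  }
  List res = List::create(_["W"] = dW, _["b"] = db);
  if (want_dx) {
    // dx_pad += shift^{-1}(dout_pad) %*% W_k^T  for each offset
    std::vector<double> dxp((size_t)npad * Cin, 0.0);
    std::vector<double> Wt((size_t)Cout * Cin);
    k = 0;
    for (int dj = -1; dj <= 1; ++dj) for (int di = -1; di <= 1; ++di, ++k) {
      const int s = dj * (H + 2) + di;
      // transpose W_k (Cin x Cout) -> (Cout x Cin)
      for (int ci = 0; ci < Cin; ++ci)
        for (int co = 0; co < Cout; ++co)
          Wt[(size_t)ci * Cout + co] = Wm(k * Cin + ci, co);
      // out[q] += xp[q+s] * Wk  =>  dxp[q+s] += dout_pad[q] * Wk^T:
      // rows q in [max(0,-s), npad - max(0,s)) of dout map to rows q+s of dxp
      const double* Dm = dop.data() + (s < 0 ? -s : 0);
      double* Cm = dxp.data() + (s > 0 ? s : 0);
      const int M = npad - (s > 0 ? s : -s);
      dgemm_shift(Dm, npad, Wt.data(), Cout, Cm, npad, M, Cout, Cin, 1.0, 1.0, 'N');
    }
    NumericMatrix dx(B * npx, Cin);
    from_padded(dxp.data(), dx, H, W, B);
    res["dx"] = dx;
  }
  return res;
}
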