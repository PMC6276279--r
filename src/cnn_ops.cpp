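// Hot paths of the screening CNN: 3x3 same-padding convolution blocks and
// 2x2 max pooling. Convolutions are computed directly as fused nine-tap
// passes over zero-padded planes: one read stream per kernel column and
// one accumulator stream, which keeps the working set in cache and
// auto-vectorizes. (im2col+GEMM is slower here: the GEMM shapes are so
// skinny that BLAS falls off its fast path.)
//
// Array layout (column-major, as R stores them) is channel-last
// throughout: inputs and activations are (H, W, C, N); conv weights are
// (F, 9C) with rows ordered (ky, kx, c), ky fastest. The R level keeps
// all randomness (init, shuffling, dropout), so training is
// deterministic for a given seed.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// copy an (H, W) plane into a zero-padded (H+2, W+2) buffer
static void pad_plane(const double* __restrict__ P, double* __restrict__ Q,
                      int H, int W) {
  const int Hp = H + 2;
  std::fill(Q, Q + (size_t)Hp * (W + 2), 0.0);
  for (int j = 0; j < W; ++j) {
    double* q = Q + (size_t)(j + 1) * Hp + 1;
    const double* p = P + (size_t)j * H;
    std::copy(p, p + H, q);
  }
}

// Z(H, W) += conv3x3(Ppad, w9); w9 ordered (ky, kx), ky fastest
static void conv9_acc(double* __restrict__ Z, const double* __restrict__ Ppad,
                      const double* __restrict__ w, int H, int W) {
  const int Hp = H + 2;
  for (int j = 0; j < W; ++j) {
    double* __restrict__ z = Z + (size_t)j * H;
    const double* __restrict__ c0 = Ppad + (size_t)j * Hp;
    const double* __restrict__ c1 = c0 + Hp;
    const double* __restrict__ c2 = c1 + Hp;
    for (int i = 0; i < H; ++i) {
      z[i] += w[0] * c0[i] + w[1] * c0[i + 1] + w[2] * c0[i + 2]
            + w[3] * c1[i] + w[4] * c1[i + 1] + w[5] * c1[i + 2]
            + w[6] * c2[i] + w[7] * c2[i + 1] + w[8] * c2[i + 2];
    }
  }
}

// out9(ky, kx) += sum_{i,j} G(i, j) * Ppad(i + ky, j + kx)
static void dot9_acc(const double* __restrict__ G,
                     const double* __restrict__ Ppad,
                     double* __restrict__ out, int H, int W) {
  const int Hp = H + 2;
  double s[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
  for (int j = 0; j < W; ++j) {
    const double* __restrict__ g = G + (size_t)j * H;
    const double* __restrict__ c0 = Ppad + (size_t)j * Hp;
    const double* __restrict__ c1 = c0 + Hp;
    const double* __restrict__ c2 = c1 + Hp;
    double t0 = 0, t1 = 0, t2 = 0, t3 = 0, t4 = 0, t5 = 0, t6 = 0, t7 = 0,
           t8 = 0;
    for (int i = 0; i < H; ++i) {
      const double gv = g[i];
      t0 += gv * c0[i]; t1 += gv * c0[i + 1]; t2 += gv * c0[i + 2];
      t3 += gv * c1[i]; t4 += gv * c1[i + 1]; t5 += gv * c1[i + 2];
      t6 += gv * c2[i]; t7 += gv * c2[i + 1]; t8 += gv * c2[i + 2];
    }
    s[0] += t0; s[1] += t1; s[2] += t2; s[3] += t3; s[4] += t4;
    s[5] += t5; s[6] += t6; s[7] += t7; s[8] += t8;
  }
  for (int r = 0; r < 9; ++r) out[r] += s[r];
}

// two accumulator planes sharing one set of source-column loads
static void conv9_acc2(double* __restrict__ Z0, double* __restrict__ Z1,
                       const double* __restrict__ Ppad,
                       const double* __restrict__ wa,
                       const double* __restrict__ wb, int H, int W) {
  const int Hp = H + 2;
  for (int j = 0; j < W; ++j) {
    double* __restrict__ z0 = Z0 + (size_t)j * H;
    double* __restrict__ z1 = Z1 + (size_t)j * H;
    const double* __restrict__ c0 = Ppad + (size_t)j * Hp;
    const double* __restrict__ c1 = c0 + Hp;
    const double* __restrict__ c2 = c1 + Hp;
    for (int i = 0; i < H; ++i) {
      const double a0 = c0[i], a1 = c0[i + 1], a2 = c0[i + 2];
      const double b0 = c1[i], b1 = c1[i + 1], b2 = c1[i + 2];
      const double d0 = c2[i], d1 = c2[i + 1], d2 = c2[i + 2];
      z0[i] += wa[0] * a0 + wa[1] * a1 + wa[2] * a2
             + wa[3] * b0 + wa[4] * b1 + wa[5] * b2
             + wa[6] * d0 + wa[7] * d1 + wa[8] * d2;
      z1[i] += wb[0] * a0 + wb[1] * a1 + wb[2] * a2
             + wb[3] * b0 + wb[4] * b1 + wb[5] * b2
             + wb[6] * d0 + wb[7] * d1 + wb[8] * d2;
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv_relu_forward")]]
NumericVector cpp_conv_relu_forward(NumericVector X, NumericMatrix Wt,
                                    NumericVector b, IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int F = Wt.nrow();
  const size_t plane = (size_t)H * W, pplane = (size_t)(H + 2) * (W + 2);
  NumericVector A(plane * F * N);
  std::vector<double> pad(pplane * C);
  double w9[9];
  const double* x = X.begin();
  double* a = A.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)n * C * plane;
    for (int c = 0; c < C; ++c)
      pad_plane(xn + (size_t)c * plane, pad.data() + (size_t)c * pplane, H, W);
    double* an = a + (size_t)n * F * plane;
    int f = 0;
    for (; f + 2 <= F; f += 2) {         // pairs of filters share loads
      double* Z0 = an + (size_t)f * plane;
      double* Z1 = Z0 + plane;
      std::fill(Z0, Z0 + plane, b[f]);
      std::fill(Z1, Z1 + plane, b[f + 1]);
      double wb9[9];
      for (int c = 0; c < C; ++c) {
        for (int r = 0; r < 9; ++r) {
          w9[r] = Wt(f, 9 * c + r);
          wb9[r] = Wt(f + 1, 9 * c + r);
        }
        conv9_acc2(Z0, Z1, pad.data() + (size_t)c * pplane, w9, wb9, H, W);
      }
      for (size_t i = 0; i < 2 * plane; ++i) if (Z0[i] < 0.0) Z0[i] = 0.0;
    }
    for (; f < F; ++f) {
      double* Z = an + (size_t)f * plane;
      std::fill(Z, Z + plane, b[f]);
      for (int c = 0; c < C; ++c) {
        for (int r = 0; r < 9; ++r) w9[r] = Wt(f, 9 * c + r);
        conv9_acc(Z, pad.data() + (size_t)c * pplane, w9, H, W);
      }
      for (size_t i = 0; i < plane; ++i) if (Z[i] < 0.0) Z[i] = 0.0;
    }
  }
  A.attr("dim") = IntegerVector::create(H, W, F, N);
  return A;
}

// [[Rcpp::export(name = ".cpp_conv_relu_backward")]]
List cpp_conv_relu_backward(NumericVector X, NumericMatrix Wt,
                            NumericVector A, NumericVector dA,
                            IntegerVector dims, bool need_dx) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int F = Wt.nrow();
  const size_t plane = (size_t)H * W, pplane = (size_t)(H + 2) * (W + 2);
  // dZ = dA * 1[A > 0]; dA is always a scratch gradient freshly produced
  // by the caller (pool backward / dense backward), so mask it in place
  NumericVector dZv(dA);
  {
    const double* av = A.begin();
    double* dz = dZv.begin();
    const size_t total = plane * F * N;
    for (size_t i = 0; i < total; ++i) if (av[i] <= 0.0) dz[i] = 0.0;
  }
  NumericMatrix dW(F, 9 * C);
  NumericVector db(F);
  const double* x = X.begin();
  const double* dz = dZv.begin();
  std::vector<double> pad(pplane * C);
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)n * C * plane;
    for (int c = 0; c < C; ++c)
      pad_plane(xn + (size_t)c * plane, pad.data() + (size_t)c * pplane, H, W);
    const double* dzn = dz + (size_t)n * F * plane;
    for (int f = 0; f < F; ++f) {
      const double* G = dzn + (size_t)f * plane;
      double s = 0.0;
      for (size_t i = 0; i < plane; ++i) s += G[i];
      db[f] += s;
      for (int c = 0; c < C; ++c) {
        double acc[9];
        for (int r = 0; r < 9; ++r) acc[r] = dW(f, 9 * c + r);
        dot9_acc(G, pad.data() + (size_t)c * pplane, acc, H, W);
        for (int r = 0; r < 9; ++r) dW(f, 9 * c + r) = acc[r];
      }
    }
  }
  List out = List::create(Named("W") = dW, Named("b") = db);
  if (need_dx) {
    // dX[., c] = sum_f conv(dZ[., f], kernel flipped in both directions)
    NumericVector dX(plane * C * N);
    std::vector<double> gpad(pplane * F);
    double w9[9];
    double* dxp = dX.begin();
    for (int n = 0; n < N; ++n) {
      const double* dzn = dz + (size_t)n * F * plane;
      for (int f = 0; f < F; ++f)
        pad_plane(dzn + (size_t)f * plane, gpad.data() + (size_t)f * pplane,
                  H, W);
      double* xn = dxp + (size_t)n * C * plane;
      int c = 0;
      for (; c + 2 <= C; c += 2) {       // pairs of channels share loads
        double* D0 = xn + (size_t)c * plane;
        double* D1 = D0 + plane;
        double wb9[9];
        for (int f = 0; f < F; ++f) {
          for (int ky = 0; ky < 3; ++ky)
            for (int kx = 0; kx < 3; ++kx) {
              w9[ky + 3 * kx] = Wt(f, (2 - ky) + 3 * (2 - kx) + 9 * c);
              wb9[ky + 3 * kx] = Wt(f, (2 - ky) + 3 * (2 - kx) + 9 * (c + 1));
            }
          conv9_acc2(D0, D1, gpad.data() + (size_t)f * pplane, w9, wb9, H, W);
        }
      }
      for (; c < C; ++c) {
        double* D = xn + (size_t)c * plane;
        for (int f = 0; f < F; ++f) {
          for (int ky = 0; ky < 3; ++ky)
            for (int kx = 0; kx < 3; ++kx)
              w9[ky + 3 * kx] = Wt(f, (2 - ky) + 3 * (2 - kx) + 9 * c);
          conv9_acc(D, gpad.data() + (size_t)f * pplane, w9, H, W);
        }
      }
    }
    dX.attr("dim") = IntegerVector::create(H, W, C, N);
    out["X"] = dX;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_maxpool_forward")]]
List cpp_maxpool_forward(NumericVector A, IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int h = H / 2, w = W / 2;
  const size_t plane = (size_t)H * W, oplane = (size_t)h * w;
  NumericVector P(oplane * C * N);
  IntegerVector which(oplane * C * N);   // 0..3 = (dy, dx) pair index
  const double* a = A.begin();
  double* p = P.begin();
  int* wh = which.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* src = a + cn * plane;
    double* dst = p + cn * oplane;
    int* dwh = wh + cn * oplane;
    for (int j = 0; j < w; ++j) {
      const double* c0 = src + (size_t)(2 * j) * H;
      const double* c1 = src + (size_t)(2 * j + 1) * H;
      double* d = dst + (size_t)j * h;
      int* dw = dwh + (size_t)j * h;
      for (int i = 0; i < h; ++i) {
        const double v00 = c0[2 * i], v10 = c0[2 * i + 1];
        const double v01 = c1[2 * i], v11 = c1[2 * i + 1];
        double best = v00; int arg = 0;
        if (v10 > best) { best = v10; arg = 1; }
        if (v01 > best) { best = v01; arg = 2; }
        if (v11 > best) { best = v11; arg = 3; }
        d[i] = best; dw[i] = arg;
      }
    }
  }
  P.attr("dim") = IntegerVector::create(h, w, C, N);
  which.attr("dim") = IntegerVector::create(h, w, C, N);
  return List::create(Named("P") = P, Named("which") = which);
}

// [[Rcpp::export(name = ".cpp_maxpool_backward")]]
NumericVector cpp_maxpool_backward(NumericVector dP, IntegerVector which,
                                   IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int h = H / 2, w = W / 2;
  const size_t plane = (size_t)H * W, oplane = (size_t)h * w;
  NumericVector dA(plane * C * N);       // zero-initialized
  const double* dp = dP.begin();
  const int* wh = which.begin();
  double* da = dA.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    double* dst = da + cn * plane;
    const double* src = dp + cn * oplane;
    const int* swh = wh + cn * oplane;
    for (int j = 0; j < w; ++j) {
      double* c0 = dst + (size_t)(2 * j) * H;
      double* c1 = dst + (size_t)(2 * j + 1) * H;
      const double* s = src + (size_t)j * h;
      const int* sw = swh + (size_t)j * h;
      for (int i = 0; i < h; ++i) {
        const int arg = sw[i];
        double* tgt = (arg & 2) ? c1 : c0;
        tgt[2 * i + (arg & 1)] += s[i];
      }
    }
  }
  dA.attr("dim") = IntegerVector::create(H, W, C, N);
  return dA;
}
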