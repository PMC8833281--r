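// Compiled kernels for the 2D U-net and mask labeling.
//
// Array conventions: feature stacks are R arrays with dim (H, W, C, N),
// column-major; conv weights are (k, k, Cin, Cout); transposed-conv
// weights are (2, 2, Cin, Cout). All convolutions are "same"-padded with
// zeros. Arithmetic is single precision internally (the gradient checks
// in the test suite size their tolerances accordingly).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static IntegerVector dims_of(const NumericVector& x) {
  if (x.attr("dim") == R_NilValue) stop("input must be a dim-ed array");
  return x.attr("dim");
}

// im2col for one sample: A(H*W, k*k*Cin); column r = ci*k*k + kw*k + kh
// holds the image plane shifted by (kh - pad, kw - pad). Row index
// p = h + H*w matches R's column-major slice layout, so each shifted
// column segment is a contiguous copy.
static void im2col(const double* x, int H, int W, int Cin, int k,
                   arma::fmat& A) {
  const int pad = (k - 1) / 2;
  A.zeros();
  for (int ci = 0; ci < Cin; ++ci) {
    const double* plane = x + (size_t)ci * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = ci * k * k + kw * k + kh;
        float* acol = A.colptr(r);
        for (int w = 0; w < W; ++w) {
          const int wi = w + kw - pad;
          if (wi < 0 || wi >= W) continue;
          const double* src = plane + (size_t)wi * H;
          float* dst = acol + (size_t)H * w;
          const int h0 = std::max(0, pad - kh);
          const int h1 = std::min(H, H + pad - kh);
          for (int h = h0; h < h1; ++h)
            dst[h] = (float)src[h + kh - pad];
        }
      }
    }
  }
}

// scatter-add of gA (H*W, k*k*Cin) back into gx (reverse of im2col)
static void col2im(const arma::fmat& gA, int H, int W, int Cin, int k,
                   double* gx) {
  const int pad = (k - 1) / 2;
  for (int ci = 0; ci < Cin; ++ci) {
    double* plane = gx + (size_t)ci * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = ci * k * k + kw * k + kh;
        const float* acol = gA.colptr(r);
        for (int w = 0; w < W; ++w) {
          const int wi = w + kw - pad;
          if (wi < 0 || wi >= W) continue;
          double* dst = plane + (size_t)wi * H;
          const float* src = acol + (size_t)H * w;
          const int h0 = std::max(0, pad - kh);
          const int h1 = std::min(H, H + pad - kh);
          for (int h = h0; h < h1; ++h)
            dst[h + kh - pad] += (double)src[h];
        }
      }
    }
  }
}

// Wt(k*k*Cin, Cout) with row index matching im2col's column index
static arma::fmat weight_mat(const NumericVector& w, int k, int Cin, int Cout) {
  arma::fmat Wt(k * k * Cin, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh)
          Wt(ci * k * k + kw * k + kh, co) =
            (float)w[kh + k * (kw + k * (ci + Cin * co))];
  return Wt;
}

// [[Rcpp::export]]
NumericVector conv_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                           bool relu) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != Cin) stop("weight dims do not match input channels");
  arma::fmat Wt = weight_mat(w, k, Cin, Cout);

  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::fmat A(H * W, k * k * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(&x[0] + (size_t)n * H * W * Cin, H, W, Cin, k, A);
    arma::fmat Y = A * Wt;            // (H*W, Cout)
    double* yp = &y[0] + (size_t)n * H * W * Cout;
    for (int co = 0; co < Cout; ++co) {
      const float bv = (float)b[co];
      const float* src = Y.colptr(co);
      double* dst = yp + (size_t)co * H * W;
      if (relu)
        for (int p = 0; p < H * W; ++p) {
          float v = src[p] + bv;
          dst[p] = v > 0.0f ? (double)v : 0.0;
        }
      else
        for (int p = 0; p < H * W; ++p) dst[p] = (double)(src[p] + bv);
    }
  }
  return y;
}

// Backward pass; relu gating uses the stored forward output y (y > 0).
// [[Rcpp::export]]
List conv_bwd_cpp(NumericVector x, NumericVector w, NumericVector y,
                  NumericVector gy, bool relu) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  arma::fmat Wt = weight_mat(w, k, Cin, Cout);

  NumericVector gx((size_t)H * W * Cin * N);
  gx.attr("dim") = xd;
  arma::fmat gW(k * k * Cin, Cout, arma::fill::zeros);
  arma::fvec gb(Cout, arma::fill::zeros);

  arma::fmat A(H * W, k * k * Cin), gY(H * W, Cout);
  for (int n = 0; n < N; ++n) {
    const double* yp = &y[0] + (size_t)n * H * W * Cout;
    const double* gp = &gy[0] + (size_t)n * H * W * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double* ysrc = yp + (size_t)co * H * W;
      const double* gsrc = gp + (size_t)co * H * W;
      float* dst = gY.colptr(co);
      float acc = 0.0f;
      for (int p = 0; p < H * W; ++p) {
        float g = (float)gsrc[p];
        if (relu && ysrc[p] <= 0.0) g = 0.0f;
        dst[p] = g;
        acc += g;
      }
      gb[co] += acc;
    }
    im2col(&x[0] + (size_t)n * H * W * Cin, H, W, Cin, k, A);
    gW += A.t() * gY;
    arma::fmat gA = gY * Wt.t();     // (H*W, k*k*Cin)
    col2im(gA, H, W, Cin, k, &gx[0] + (size_t)n * H * W * Cin);
  }

  NumericVector gwv((size_t)k * k * Cin * Cout);
  gwv.attr("dim") = wd;
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh)
          gwv[kh + k * (kw + k * (ci + Cin * co))] =
            (double)gW(ci * k * k + kw * k + kh, co);
  NumericVector gbv(Cout);
  for (int i = 0; i < Cout; ++i) gbv[i] = (double)gb[i];
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gbv);
}

// 2x2 max pooling, stride 2. idx stores the winning offset (0..3) per
// output element: offset = dh + 2*dw.
// [[Rcpp::export]]
List pool_fwd_cpp(NumericVector x) {
  IntegerVector xd = dims_of(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("pooling requires even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* plane = &x[0] + ((size_t)c + (size_t)C * n) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              double v = plane[(2 * h + dh) + (size_t)H * (2 * w + dw)];
              if (v > best) { best = v; bi = dh + 2 * dw; }
            }
          size_t oi = (size_t)h + (size_t)Ho * (w + (size_t)Wo * (c + (size_t)C * n));
          y[oi] = best;
          idx[oi] = bi;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector pool_bwd_cpp(NumericVector gy, IntegerVector idx, int H, int W) {
  IntegerVector yd = dims_of(gy);
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* plane = &gx[0] + ((size_t)c + (size_t)C * n) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          size_t oi = (size_t)h + (size_t)Ho * (w + (size_t)Wo * (c + (size_t)C * n));
          int bi = idx[oi];
          int dh = bi % 2, dw = bi / 2;
          plane[(2 * h + dh) + (size_t)H * (2 * w + dw)] += gy[oi];
        }
    }
  return gx;
}

// Transposed conv 2x2, stride 2: upsamples (H,W) -> (2H,2W).
// Wm2(q, ci) with q = (dh + 2*dw) + 4*co.
static arma::fmat upweight_mat(const NumericVector& w, int Cin, int Cout) {
  arma::fmat Wm(4 * Cout, Cin);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int dw = 0; dw < 2; ++dw)
        for (int dh = 0; dh < 2; ++dh)
          Wm((dh + 2 * dw) + 4 * co, ci) =
            (float)w[dh + 2 * (dw + 2 * (ci + Cin * co))];
  return Wm;
}

// [[Rcpp::export]]
NumericVector upconv_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             bool relu) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int Cout = wd[3];
  arma::fmat Wm = upweight_mat(w, Cin, Cout);
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::fmat X(Cin, H * W);
  for (int n = 0; n < N; ++n) {
    const double* xp = &x[0] + (size_t)n * H * W * Cin;
    for (int ci = 0; ci < Cin; ++ci)
      for (int p = 0; p < H * W; ++p)
        X(ci, p) = (float)xp[(size_t)ci * H * W + p];
    arma::fmat Y4 = Wm * X;  // (4*Cout, H*W)
    double* yp = &y[0] + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      const float bv = (float)b[co];
      double* plane = yp + (size_t)co * Ho * Wo;
      for (int w2 = 0; w2 < W; ++w2)
        for (int h2 = 0; h2 < H; ++h2) {
          const int p = h2 + H * w2;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              float v = Y4((dh + 2 * dw) + 4 * co, p) + bv;
              if (relu && v < 0.0f) v = 0.0f;
              plane[(2 * h2 + dh) + (size_t)Ho * (2 * w2 + dw)] = (double)v;
            }
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
List upconv_bwd_cpp(NumericVector x, NumericVector w, NumericVector y,
                    NumericVector gy, bool relu) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int Cout = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  arma::fmat Wm = upweight_mat(w, Cin, Cout);

  NumericVector gx((size_t)H * W * Cin * N);
  gx.attr("dim") = xd;
  arma::fmat gW(4 * Cout, Cin, arma::fill::zeros);
  arma::fvec gb(Cout, arma::fill::zeros);
  arma::fmat X(Cin, H * W), G4(4 * Cout, H * W);

  for (int n = 0; n < N; ++n) {
    const double* xp = &x[0] + (size_t)n * H * W * Cin;
    for (int ci = 0; ci < Cin; ++ci)
      for (int p = 0; p < H * W; ++p)
        X(ci, p) = (float)xp[(size_t)ci * H * W + p];
    const double* yp = &y[0] + (size_t)n * Ho * Wo * Cout;
    const double* gp = &gy[0] + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double* yplane = yp + (size_t)co * Ho * Wo;
      const double* gplane = gp + (size_t)co * Ho * Wo;
      for (int w2 = 0; w2 < W; ++w2)
        for (int h2 = 0; h2 < H; ++h2) {
          const int p = h2 + H * w2;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              size_t oi = (2 * h2 + dh) + (size_t)Ho * (2 * w2 + dw);
              float g = (float)gplane[oi];
              if (relu && yplane[oi] <= 0.0) g = 0.0f;
              G4((dh + 2 * dw) + 4 * co, p) = g;
              gb[co] += g;
            }
        }
    }
    gW += G4 * X.t();
    arma::fmat gX = Wm.t() * G4;  // (Cin, H*W)
    double* gxp = &gx[0] + (size_t)n * H * W * Cin;
    for (int ci = 0; ci < Cin; ++ci)
      for (int p = 0; p < H * W; ++p)
        gxp[(size_t)ci * H * W + p] += (double)gX(ci, p);
  }

  NumericVector gwv((size_t)4 * Cin * Cout);
  gwv.attr("dim") = wd;
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int dw = 0; dw < 2; ++dw)
        for (int dh = 0; dh < 2; ++dh)
          gwv[dh + 2 * (dw + 2 * (ci + Cin * co))] =
            (double)gW((dh + 2 * dw) + 4 * co, ci);
  NumericVector gbv(Cout);
  for (int i = 0; i < Cout; ++i) gbv[i] = (double)gb[i];
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gbv);
}

// 8-connected component labeling of a binary matrix (0/1). Labels are
// assigned in column-major scan order starting from 1.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (mask(h, w) == 0 || lab(h, w) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(h + H * w);
      lab(h, w) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int ph = p % H, pw = p / H;
        for (int dw = -1; dw <= 1; ++dw)
          for (int dh = -1; dh <= 1; ++dh) {
            if (dh == 0 && dw == 0) continue;
            int nh = ph + dh, nw = pw + dw;
            if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
            if (mask(nh, nw) != 0 && lab(nh, nw) == 0) {
              lab(nh, nw) = next;
              stack.push_back(nh + H * nw);
            }
          }
      }
    }
  return lab;
}
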