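// Hot kernels of the network: 2-D convolution (forward, and backward w.r.t.
// data and weights) and max-pooling, over arrays laid out (H, W, C, N) in
// R's column-major order. Convolution is im2col + GEMM per sample so the
// work lands in BLAS; the im2col buffer is reused across the batch.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void fill_cols(const double* xn, arma::mat& cols,
                      int H, int W, int C, int kh, int kw,
                      int sh, int sw, int ph, int pw,
                      int Hout, int Wout) {
  for (int jo = 0; jo < Wout; ++jo) {
    for (int io = 0; io < Hout; ++io) {
      double* cp = cols.colptr(io + jo * Hout);
      for (int c = 0; c < C; ++c) {
        for (int b = 0; b < kw; ++b) {
          const int jj = jo * sw + b - pw;
          const bool jin = (jj >= 0 && jj < W);
          for (int a = 0; a < kh; ++a) {
            const int ii = io * sh + a - ph;
            const int r = a + kh * (b + kw * c);
            cp[r] = (jin && ii >= 0 && ii < H)
              ? xn[ii + (size_t)H * (jj + (size_t)W * c)] : 0.0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             int sh, int sw, int ph, int pw) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  if (xd.size() != 4 || wd.size() != 4) stop("expected 4-d input and kernel");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("kernel input channels (%d) != feature channels (%d)", Cin, C);
  const int Hout = (H + 2 * ph - kh) / sh + 1;
  const int Wout = (W + 2 * pw - kw) / sw + 1;
  if (H + 2 * ph < kh || W + 2 * pw < kw)
    stop("input (%dx%d) smaller than kernel (%dx%d) after padding", H, W, kh, kw);
  const int kkC = kh * kw * C, P = Hout * Wout;

  arma::mat Wm(const_cast<double*>(w.begin()), kkC, Cout, false, true);
  NumericVector y((size_t)P * Cout * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, Cout, N);
  arma::mat cols(kkC, P);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    fill_cols(xp + (size_t)n * H * W * C, cols, H, W, C, kh, kw,
              sh, sw, ph, pw, Hout, Wout);
    arma::mat Yn(yp + (size_t)n * P * Cout, P, Cout, false, true);
    Yn = cols.t() * Wm;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int sh, int sw, int ph, int pw) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Hout = yd[0], Wout = yd[1];
  if (yd[2] != Cout || yd[3] != N) stop("gradient shape mismatch");
  const int kkC = kh * kw * C, P = Hout * Wout;

  arma::mat Wm(const_cast<double*>(w.begin()), kkC, Cout, false, true);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dW(w.size());
  dW.attr("dim") = wd;
  arma::mat dWm(dW.begin(), kkC, Cout, false, true);
  arma::mat cols(kkC, P);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n) {
    fill_cols(xp + (size_t)n * H * W * C, cols, H, W, C, kh, kw,
              sh, sw, ph, pw, Hout, Wout);
    arma::mat dYn(const_cast<double*>(dyp) + (size_t)n * P * Cout,
                  P, Cout, false, true);
    dWm += cols * dYn;
    arma::mat dcols = Wm * dYn.t();  // kkC x P
    double* dxn = dxp + (size_t)n * H * W * C;
    for (int jo = 0; jo < Wout; ++jo) {
      for (int io = 0; io < Hout; ++io) {
        const double* dcp = dcols.colptr(io + jo * Hout);
        for (int c = 0; c < C; ++c) {
          for (int b = 0; b < kw; ++b) {
            const int jj = jo * sw + b - pw;
            if (jj < 0 || jj >= W) continue;
            for (int a = 0; a < kh; ++a) {
              const int ii = io * sh + a - ph;
              if (ii < 0 || ii >= H) continue;
              dxn[ii + (size_t)H * (jj + (size_t)W * c)] +=
                dcp[a + kh * (b + kw * c)];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW);
}

// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int kh, int kw,
                     int sh, int sw, int ph, int pw) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Hout = (H + 2 * ph - kh) / sh + 1;
  const int Wout = (W + 2 * pw - kw) / sw + 1;
  if (H + 2 * ph < kh || W + 2 * pw < kw) stop("input smaller than pooling kernel");
  NumericVector y((size_t)Hout * Wout * C * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, C, N);
  // 0-based linear index into x of each output's argmax (padding never wins
  // because at least one in-bounds element exists for valid ph < kh, pw < kw)
  IntegerVector amax(y.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int jo = 0; jo < Wout; ++jo) {
        for (int io = 0; io < Hout; ++io) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int b = 0; b < kw; ++b) {
            const int jj = jo * sw + b - pw;
            if (jj < 0 || jj >= W) continue;
            for (int a = 0; a < kh; ++a) {
              const int ii = io * sh + a - ph;
              if (ii < 0 || ii >= H) continue;
              const size_t idx = base + ii + (size_t)H * jj;
              if (xp[idx] > best) { best = xp[idx]; bidx = idx; }
            }
          }
          // write in (Hout,Wout,C,N) order: io fastest within this loop nest
          const size_t oo = (size_t)io + (size_t)Hout * (jo + (size_t)Wout * (c + (size_t)C * n));
          yp[oo] = best;
          amax[oo] = (int)bidx;
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dy, IntegerVector amax,
                              IntegerVector xdim) {
  size_t nx = 1;
  for (int i = 0; i < xdim.size(); ++i) nx *= (size_t)xdim[i];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) dxp[amax[i]] += dyp[i];
  return dx;
}
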