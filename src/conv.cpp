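#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 2-D convolution primitives on H x W x C arrays (column-major, as stored by R).
// Weights are kh x kw x Cin x Cout. Zero padding, integer stride.
// These three routines are the building blocks of both the forward pass and
// backpropagation; a transposed convolution is conv2d_bwd_input run forward.

static inline int idx3(int i, int j, int c, int H, int W) {
  return i + H * (j + (long)W * c);
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("channel mismatch: input has %d, kernel expects %d", Cin, wd[2]);
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector y(Ho * (long)Wo * Cout);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *py = y.begin();
  for (int co = 0; co < Cout; ++co) {
    for (int jo = 0; jo < Wo; ++jo) {
      int j0 = jo * stride - pad;
      for (int io = 0; io < Ho; ++io) {
        int i0 = io * stride - pad;
        double acc = pb[co];
        for (int ci = 0; ci < Cin; ++ci) {
          for (int kj = 0; kj < kw; ++kj) {
            int j = j0 + kj;
            if (j < 0 || j >= W) continue;
            const double *xc = px + H * (j + (long)W * ci);
            const double *wc = pw + kh * (kj + kw * (ci + (long)Cin * co));
            for (int ki = 0; ki < kh; ++ki) {
              int i = i0 + ki;
              if (i < 0 || i >= H) continue;
              acc += xc[i] * wc[ki];
            }
          }
        }
        py[idx3(io, jo, co, Ho, Wo)] = acc;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd_input")]]
NumericVector conv2d_bwd_input(NumericVector dy, NumericVector w,
                               int stride, int pad, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  IntegerVector wd = w.attr("dim");
  int Ho = yd[0], Wo = yd[1], Cout = yd[2];
  int kh = wd[0], kw = wd[1], Cin = wd[2];
  if (wd[3] != Cout) stop("channel mismatch in conv backward");
  NumericVector dx(H * (long)W * Cin);
  dx.attr("dim") = IntegerVector::create(H, W, Cin);
  const double *pdy = dy.begin(), *pw = w.begin();
  double *pdx = dx.begin();
  for (int co = 0; co < Cout; ++co) {
    for (int jo = 0; jo < Wo; ++jo) {
      int j0 = jo * stride - pad;
      for (int io = 0; io < Ho; ++io) {
        int i0 = io * stride - pad;
        double g = pdy[idx3(io, jo, co, Ho, Wo)];
        if (g == 0.0) continue;
        for (int ci = 0; ci < Cin; ++ci) {
          for (int kj = 0; kj < kw; ++kj) {
            int j = j0 + kj;
            if (j < 0 || j >= W) continue;
            double *xc = pdx + H * (j + (long)W * ci);
            const double *wc = pw + kh * (kj + kw * (ci + (long)Cin * co));
            for (int ki = 0; ki < kh; ++ki) {
              int i = i0 + ki;
              if (i < 0 || i >= H) continue;
              xc[i] += g * wc[ki];
            }
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export(name = ".conv2d_bwd_weights")]]
NumericVector conv2d_bwd_weights(NumericVector x, NumericVector dy,
                                 int kh, int kw, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector yd = dy.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int Ho = yd[0], Wo = yd[1], Cout = yd[2];
  NumericVector dw(kh * (long)kw * Cin * Cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  const double *px = x.begin(), *pdy = dy.begin();
  double *pdw = dw.begin();
  for (int co = 0; co < Cout; ++co) {
    for (int jo = 0; jo < Wo; ++jo) {
      int j0 = jo * stride - pad;
      for (int io = 0; io < Ho; ++io) {
        int i0 = io * stride - pad;
        double g = pdy[idx3(io, jo, co, Ho, Wo)];
        if (g == 0.0) continue;
        for (int ci = 0; ci < Cin; ++ci) {
          for (int kj = 0; kj < kw; ++kj) {
            int j = j0 + kj;
            if (j < 0 || j >= W) continue;
            const double *xc = px + H * (j + (long)W * ci);
            double *wc = pdw + kh * (kj + kw * (ci + (long)Cin * co));
            for (int ki = 0; ki < kh; ++ki) {
              int i = i0 + ki;
              if (i < 0 || i >= H) continue;
              wc[ki] += g * xc[i];
            }
          }
        }
      }
    }
  }
  return dw;
}

// 8-connected component labeling of a logical matrix (one axial slice).
// Iterative flood fill; labels are 1..n in scan order, background 0.
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + H * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj) {
          int nj = pj + dj;
          if (nj < 0 || nj >= W) continue;
          for (int di = -1; di <= 1; ++di) {
            int ni = pi + di;
            if (ni < 0 || ni >= H || (di == 0 && dj == 0)) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back(ni + H * nj);
            }
          }
        }
      }
    }
  }
  return lab;
}
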