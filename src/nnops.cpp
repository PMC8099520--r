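// Dense spatial primitives for the bit-plane predictor networks.
//
// A feature map is a NumericMatrix of shape (H*W) x C: column c holds channel
// c in column-major raster order (flat index p = r + col*H, 0-based).
// Convolution weights are (9*Cin) x Cout with row k*Cin + ci, where k indexes
// the 3x3 offset (dr, dc) as k = (dc+1)*3 + (dr+1). Zero padding of one pixel
// keeps the spatial size ("same" convolution).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_conv3x3_fwd")]]
NumericMatrix cpp_conv3x3_fwd(NumericMatrix x, int H, int W,
                              NumericMatrix wt, NumericVector bias) {
  const int cin = x.ncol(), cout = wt.ncol();
  if (x.nrow() != H * W) stop("conv: x has wrong spatial size");
  if (wt.nrow() != 9 * cin) stop("conv: weight/channel mismatch");
  NumericMatrix y(H * W, cout);
  for (int co = 0; co < cout; ++co) {
    double* yp = &y(0, co);
    const double b = bias[co];
    for (int p = 0; p < H * W; ++p) yp[p] = b;
    for (int k = 0; k < 9; ++k) {
      const int dr = k % 3 - 1, dc = k / 3 - 1;
      const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
      const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      for (int ci = 0; ci < cin; ++ci) {
        const double w = wt(k * cin + ci, co);
        if (w == 0.0) continue;
        const double* xp = &x(0, ci);
        for (int c = c0; c < c1; ++c) {
          const int dst = c * H, src = dst + dr + dc * H;
          for (int r = r0; r < r1; ++r) yp[dst + r] += w * xp[src + r];
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv3x3_bwd")]]
List cpp_conv3x3_bwd(NumericMatrix x, int H, int W,
                     NumericMatrix wt, NumericMatrix dy) {
  const int cin = x.ncol(), cout = wt.ncol();
  if (dy.nrow() != H * W || dy.ncol() != cout) stop("conv bwd: dy shape");
  NumericMatrix dx(H * W, cin), dw(9 * cin, cout);
  NumericVector db(cout);
  for (int co = 0; co < cout; ++co) {
    const double* dyp = &dy(0, co);
    double acc = 0.0;
    for (int p = 0; p < H * W; ++p) acc += dyp[p];
    db[co] = acc;
    for (int k = 0; k < 9; ++k) {
      const int dr = k % 3 - 1, dc = k / 3 - 1;
      const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
      const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      for (int ci = 0; ci < cin; ++ci) {
        const double w = wt(k * cin + ci, co);
        const double* xp = &x(0, ci);
        double* dxp = &dx(0, ci);
        double g = 0.0;
        for (int c = c0; c < c1; ++c) {
          const int dst = c * H, src = dst + dr + dc * H;
          for (int r = r0; r < r1; ++r) {
            const double d = dyp[dst + r];
            g += xp[src + r] * d;
            dxp[src + r] += w * d;
          }
        }
        dw(k * cin + ci, co) = g;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled map and the 0-based flat argmax
// index into the input (per output position and channel) for the backward pass.

// [[Rcpp::export(name = ".cpp_maxpool2_fwd")]]
List cpp_maxpool2_fwd(NumericMatrix x, int H, int W) {
  if (H % 2 || W % 2) stop("maxpool: odd spatial size");
  const int cin = x.ncol(), h = H / 2, w = W / 2;
  NumericMatrix y(h * w, cin);
  IntegerMatrix idx(h * w, cin);
  for (int ci = 0; ci < cin; ++ci) {
    const double* xp = &x(0, ci);
    for (int c = 0; c < w; ++c) {
      for (int r = 0; r < h; ++r) {
        const int base = 2 * r + 2 * c * H;
        int best = base;
        double v = xp[base];
        const int cand[3] = { base + 1, base + H, base + H + 1 };
        for (int t = 0; t < 3; ++t)
          if (xp[cand[t]] > v) { v = xp[cand[t]]; best = cand[t]; }
        y(r + c * h, ci) = v;
        idx(r + c * h, ci) = best;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bwd")]]
NumericMatrix cpp_maxpool2_bwd(NumericMatrix dy, IntegerMatrix idx, int HW) {
  const int cin = dy.ncol();
  NumericMatrix dx(HW, cin);
  for (int ci = 0; ci < cin; ++ci)
    for (int p = 0; p < dy.nrow(); ++p)
      dx(idx(p, ci), ci) += dy(p, ci);
  return dx;
}
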