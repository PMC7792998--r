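// Low-level numerical kernels: 2D convolution layers via im2col + GEMM,
// 2x2 max pooling, nearest-neighbour upsampling, and reliability-ordered
// region-growing 2D phase unwrapping.
//
// Array layout convention (R column-major):
//   activations x: dim (H, W, C, N)
//   weights    W: dim (kh, kw, Cin, Cout), odd kernel extents, stride 1,
//                 "same" zero padding
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4D array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Fill the im2col matrix (kh*kw*Cin x H*W) for sample n.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, arma::mat& M) {
  const int ph = kh / 2, pw = kw / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int row = i + kh * (j + kw * c);
        for (int w = 0; w < W; ++w) {
          const int ws = w + j - pw;
          double* Mcol = M.memptr() + (size_t)row + (size_t)M.n_rows * (size_t)w * H;
          if (ws < 0 || ws >= W) {
            for (int h = 0; h < H; ++h) Mcol[(size_t)M.n_rows * h] = 0.0;
          } else {
            const double* xcol = xc + (size_t)ws * H;
            for (int h = 0; h < H; ++h) {
              const int hs = h + i - ph;
              Mcol[(size_t)M.n_rows * h] =
                (hs < 0 || hs >= H) ? 0.0 : xcol[hs];
            }
          }
        }
      }
    }
  }
}

// Scatter-add of a col-matrix gradient back onto the input image (adjoint of im2col).
static void col2im(const arma::mat& M, int H, int W, int C,
                   int kh, int kw, double* gx) {
  const int ph = kh / 2, pw = kw / 2;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int row = i + kh * (j + kw * c);
        for (int w = 0; w < W; ++w) {
          const int ws = w + j - pw;
          if (ws < 0 || ws >= W) continue;
          const double* Mcol = M.memptr() + (size_t)row + (size_t)M.n_rows * (size_t)w * H;
          double* gcol = gc + (size_t)ws * H;
          for (int h = 0; h < H; ++h) {
            const int hs = h + i - ph;
            if (hs >= 0 && hs < H) gcol[hs] += Mcol[(size_t)M.n_rows * h];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector Wt, NumericVector b) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = Wt.attr("dim");
  if (wd.size() != 4) stop("weights must be 4D (kh, kw, Cin, Cout)");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("input channels mismatch");
  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(const_cast<double*>(Wt.begin()), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat M((size_t)kh * kw * Cin, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, M);
    arma::mat Y(y.begin() + (size_t)n * H * W * Cout, (size_t)H * W, Cout, false, true);
    Y = M.t() * Wm;                      // (H*W x Cout), h fastest: matches layout
    for (int c = 0; c < Cout; ++c) Y.col(c) += b[c];
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector Wt, NumericVector gy) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = Wt.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector gW(Wt.size());
  gW.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat Wm(const_cast<double*>(Wt.begin()), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat gWm(gW.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat M((size_t)kh * kw * Cin, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)n * H * W * Cout,
                 (size_t)H * W, Cout, false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, M);
    gWm += M * Gy;
    for (int c = 0; c < Cout; ++c) gb[c] += arma::accu(Gy.col(c));
    arma::mat Gm = Wm * Gy.t();          // (khkwCin x H*W)
    col2im(Gm, H, W, C, kh, kw, gx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool2 needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector amax(y.size());        // linear index into x of each max
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          double best = R_NegInf; size_t bi = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              const size_t idx = base + (size_t)(2 * w + dw) * H + (2 * h + dh);
              if (x[idx] > best) { best = x[idx]; bi = idx; }
            }
          y[o] = best; amax[o] = (int)bi; ++o;
        }
    }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector gy, IntegerVector amax, IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[amax[i]] += gy[i];
  return gx;
}

// [[Rcpp::export]]
NumericVector upsample2_fwd(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bi = ((size_t)n * C + c) * H * W;
      const size_t bo = ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double v = x[bi + (size_t)w * H + h];
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh)
              y[bo + (size_t)(2 * w + dw) * Ho + (2 * h + dh)] = v;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd(NumericVector gy) {
  int Ho, Wo, C, N; get_dims4(gy, Ho, Wo, C, N);
  const int H = Ho / 2, W = Wo / 2;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bi = ((size_t)n * C + c) * H * W;
      const size_t bo = ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double s = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh)
              s += gy[bo + (size_t)(2 * w + dw) * Ho + (2 * h + dh)];
          gx[bi + (size_t)w * H + h] = s;
        }
    }
  return gx;
}

// ---------------- 2D phase unwrapping (reliability-ordered region growing) --

static inline double wrap_d(double d) {
  while (d > M_PI) d -= 2 * M_PI;
  while (d <= -M_PI) d += 2 * M_PI;
  return d;
}

struct Edge { double rel; int p, q; };

// Returns the integer wrap-count field k so that phase + 2*pi*k is unwrapped.
// [[Rcpp::export]]
IntegerMatrix unwrap2d_cpp(NumericMatrix phase, IntegerMatrix mask) {
  const int H = phase.nrow(), W = phase.ncol();
  const int np = H * W;
  std::vector<double> rel(np, 0.0);
  // pixel reliability: inverse of the root-sum-square of wrapped second
  // differences (horizontal, vertical, two diagonals); border/masked pixels
  // get low reliability
  auto ph = [&](int h, int w) { return phase[(size_t)w * H + h]; };
  auto inm = [&](int h, int w) {
    return h >= 0 && h < H && w >= 0 && w < W && mask[(size_t)w * H + h];
  };
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (!mask[(size_t)w * H + h]) continue;
      double D = 1e3;  // low-reliability default at borders
      if (inm(h - 1, w) && inm(h + 1, w) && inm(h, w - 1) && inm(h, w + 1) &&
          inm(h - 1, w - 1) && inm(h + 1, w + 1) && inm(h - 1, w + 1) && inm(h + 1, w - 1)) {
        const double Hd = wrap_d(ph(h, w - 1) - ph(h, w)) - wrap_d(ph(h, w) - ph(h, w + 1));
        const double Vd = wrap_d(ph(h - 1, w) - ph(h, w)) - wrap_d(ph(h, w) - ph(h + 1, w));
        const double D1 = wrap_d(ph(h - 1, w - 1) - ph(h, w)) - wrap_d(ph(h, w) - ph(h + 1, w + 1));
        const double D2 = wrap_d(ph(h - 1, w + 1) - ph(h, w)) - wrap_d(ph(h, w) - ph(h + 1, w - 1));
        D = std::sqrt(Hd * Hd + Vd * Vd + D1 * D1 + D2 * D2) + 1e-12;
      }
      rel[(size_t)w * H + h] = 1.0 / D;
    }
  std::vector<Edge> edges;
  edges.reserve((size_t)2 * np);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      const int p = w * H + h;
      if (!mask[p]) continue;
      if (h + 1 < H && mask[p + 1])
        edges.push_back({rel[p] + rel[p + 1], p, p + 1});
      if (w + 1 < W && mask[p + H])
        edges.push_back({rel[p] + rel[p + H], p, p + H});
    }
  std::stable_sort(edges.begin(), edges.end(),
                   [](const Edge& a, const Edge& b) { return a.rel > b.rel; });
  std::vector<int> group(np), kcnt(np, 0);
  std::vector<std::vector<int> > members(np);
  for (int i = 0; i < np; ++i) { group[i] = i; members[i].push_back(i); }
  for (const Edge& e : edges) {
    int gp = group[e.p], gq = group[e.q];
    if (gp == gq) continue;
    // shift group q so the edge difference is principal
    const double up = phase[e.p] + 2 * M_PI * kcnt[e.p];
    const double uq = phase[e.q] + 2 * M_PI * kcnt[e.q];
    const double want = wrap_d(phase[e.q] - phase[e.p]);
    const int m = (int)std::lround((up + want - uq) / (2 * M_PI));
    if (members[gp].size() < members[gq].size()) {
      // relabel the smaller group: move p's group onto q's frame instead
      const int minv = -m;
      for (int pix : members[gp]) { kcnt[pix] += minv; group[pix] = gq; members[gq].push_back(pix); }
      members[gp].clear();
    } else {
      for (int pix : members[gq]) { kcnt[pix] += m; group[pix] = gp; members[gp].push_back(pix); }
      members[gq].clear();
    }
  }
  IntegerMatrix K(H, W);
  for (int i = 0; i < np; ++i) K[i] = mask[i] ? kcnt[i] : 0;
  return K;
}
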