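// Core numerical kernels: 3x3 same-padded convolution (forward/backward via
// im2col + GEMM), 2x2 average pooling, 2x bilinear upsampling with exact
// adjoint, displacement-field warping, windowed normalized cross-correlation
// block matching with parabolic sub-pixel refinement, template NCC, and
// even-odd polygon rasterization.
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

// im2col for a 3x3 kernel with same padding (pad = 1) and given stride,
// transposed layout: row oj*Ho+oi holds the receptive field of output pixel
// (oi, oj); column c*9 + ky*3 + kx holds input channel c at kernel offset
// (ky, kx). The transposed layout makes the inner oi-loop contiguous in both
// source and destination, so the stride-1 path is a straight memcpy.
static mat im2col3t(const cube& x, const int stride) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H - 1) / stride + 1;
  const int Wo = (W - 1) / stride + 1;
  mat cols((size_t)Ho * Wo, C * 9, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int ky = 0; ky < 3; ++ky) {
      for (int kx = 0; kx < 3; ++kx) {
        const int q = c * 9 + ky * 3 + kx;
        double* dst0 = cols.colptr(q);
        if (stride == 1) {
          const int lo = std::max(0, 1 - ky);       // oi range with ii in [0, H)
          const int hi = std::min(H - 1, H - ky);
          const int len = hi - lo + 1;
          for (int oj = 0; oj < Wo; ++oj) {
            const int ij = oj + kx - 1;
            if (ij < 0 || ij >= W) continue;
            std::memcpy(dst0 + (size_t)oj * Ho + lo,
                        xc.colptr(ij) + lo + ky - 1, len * sizeof(double));
          }
        } else {
          for (int oj = 0; oj < Wo; ++oj) {
            const int ij = oj * stride + kx - 1;
            if (ij < 0 || ij >= W) continue;
            const double* src = xc.colptr(ij);
            double* dst = dst0 + (size_t)oj * Ho;
            for (int oi = 0; oi < Ho; ++oi) {
              const int ii = oi * stride + ky - 1;
              if (ii >= 0 && ii < H) dst[oi] = src[ii];
            }
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col3t: scatter-add the (N x C*9) matrix back onto the grid.
static cube col2im3t(const mat& cols, const int H, const int W, const int C,
                     const int stride) {
  const int Ho = (H - 1) / stride + 1;
  const int Wo = (W - 1) / stride + 1;
  cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& xc = x.slice(c);
    for (int ky = 0; ky < 3; ++ky) {
      for (int kx = 0; kx < 3; ++kx) {
        const int q = c * 9 + ky * 3 + kx;
        const double* src0 = cols.colptr(q);
        if (stride == 1) {
          const int lo = std::max(0, 1 - ky);
          const int hi = std::min(H - 1, H - ky);
          for (int oj = 0; oj < Wo; ++oj) {
            const int ij = oj + kx - 1;
            if (ij < 0 || ij >= W) continue;
            double* dst = xc.colptr(ij) + ky - 1;
            const double* src = src0 + (size_t)oj * Ho;
            for (int oi = lo; oi <= hi; ++oi) dst[oi] += src[oi];
          }
        } else {
          for (int oj = 0; oj < Wo; ++oj) {
            const int ij = oj * stride + kx - 1;
            if (ij < 0 || ij >= W) continue;
            double* dst = xc.colptr(ij);
            const double* src = src0 + (size_t)oj * Ho;
            for (int oi = 0; oi < Ho; ++oi) {
              const int ii = oi * stride + ky - 1;
              if (ii >= 0 && ii < H) dst[ii] += src[oi];
            }
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube sm_conv2d_fwd(const arma::cube& x, const arma::mat& W,
                         const arma::vec& b, const int stride) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Ho = (H - 1) / stride + 1;
  const int Wo = (Wd - 1) / stride + 1;
  const int Cout = W.n_rows;
  mat cols = im2col3t(x, stride);
  mat y = cols * W.t();        // (Ho*Wo) x Cout
  cube out(Ho, Wo, Cout);
  for (int co = 0; co < Cout; ++co) {
    std::memcpy(out.slice(co).memptr(), y.colptr(co),
                (size_t)Ho * Wo * sizeof(double));
    out.slice(co) += b(co);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List sm_conv2d_bwd(const arma::cube& x, const arma::mat& W,
                         const arma::cube& gy, const int stride,
                         const bool paramGrads = true) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int Ho = gy.n_rows, Wo = gy.n_cols, Cout = gy.n_slices;
  mat gmat((size_t)Ho * Wo, Cout);
  for (int co = 0; co < Cout; ++co)
    std::memcpy(gmat.colptr(co), gy.slice(co).memptr(),
                (size_t)Ho * Wo * sizeof(double));
  mat gcols = gmat * W;        // N x C*9
  cube gx = col2im3t(gcols, H, Wd, C, stride);
  if (!paramGrads)
    return Rcpp::List::create(Rcpp::Named("gx") = gx);
  mat cols = im2col3t(x, stride);
  mat gW = gmat.t() * cols;
  vec gb = arma::sum(gmat, 0).t();
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
arma::cube sm_avgpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        y(i, j, c) = 0.25 * (x(2 * i, 2 * j, c) + x(2 * i + 1, 2 * j, c) +
                             x(2 * i, 2 * j + 1, c) + x(2 * i + 1, 2 * j + 1, c));
  return y;
}

// [[Rcpp::export]]
arma::cube sm_avgpool2_bwd(const arma::cube& gy) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  cube gx(2 * Ho, 2 * Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double g = 0.25 * gy(i, j, c);
        gx(2 * i, 2 * j, c) = g;
        gx(2 * i + 1, 2 * j, c) = g;
        gx(2 * i, 2 * j + 1, c) = g;
        gx(2 * i + 1, 2 * j + 1, c) = g;
      }
  return gx;
}

// Half-pixel-center source coordinates for 2x bilinear upsampling; edge
// samples clamp, so the map is exactly linear and its adjoint is a scatter.
static void up2_coords(const int n, const int N, arma::ivec& i0, arma::ivec& i1,
                       arma::vec& w1) {
  i0.set_size(N); i1.set_size(N); w1.set_size(N);
  for (int i = 0; i < N; ++i) {
    double s = (i + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > n - 1) s = n - 1;
    int lo = (int)std::floor(s);
    if (lo > n - 2) lo = n - 2;
    if (n == 1) { i0(i) = 0; i1(i) = 0; w1(i) = 0; continue; }
    i0(i) = lo; i1(i) = lo + 1; w1(i) = s - lo;
  }
}

// [[Rcpp::export]]
arma::cube sm_upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = 2 * H, Wo = 2 * W;
  arma::ivec r0, r1, c0, c1; arma::vec wr, wc;
  up2_coords(H, Ho, r0, r1, wr);
  up2_coords(W, Wo, c0, c1, wc);
  cube y(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double a = xc(r0(i), c0(j)), bb = xc(r1(i), c0(j));
        const double cc = xc(r0(i), c1(j)), d = xc(r1(i), c1(j));
        y(i, j, c) = (1 - wr(i)) * ((1 - wc(j)) * a + wc(j) * cc) +
                     wr(i) * ((1 - wc(j)) * bb + wc(j) * d);
      }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube sm_upsample2_bwd(const arma::cube& gy) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  const int H = Ho / 2, W = Wo / 2;
  arma::ivec r0, r1, c0, c1; arma::vec wr, wc;
  up2_coords(H, Ho, r0, r1, wr);
  up2_coords(W, Wo, c0, c1, wc);
  cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& gc = gx.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double g = gy(i, j, c);
        gc(r0(i), c0(j)) += (1 - wr(i)) * (1 - wc(j)) * g;
        gc(r1(i), c0(j)) += wr(i) * (1 - wc(j)) * g;
        gc(r0(i), c1(j)) += (1 - wr(i)) * wc(j) * g;
        gc(r1(i), c1(j)) += wr(i) * wc(j) * g;
      }
  }
  return gx;
}

// Warp: out(p) = img(p - field(p)); field slice 0 = row shift, slice 1 = col
// shift; out-of-bounds samples clamp to the nearest edge pixel.
// [[Rcpp::export]]
arma::cube sm_warp(const arma::cube& img, const arma::cube& field,
                   const bool bilinear) {
  const int H = img.n_rows, W = img.n_cols, C = img.n_slices;
  cube out(H, W, C);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double si = i - field(i, j, 0);
      double sj = j - field(i, j, 1);
      if (si < 0) si = 0; if (si > H - 1) si = H - 1;
      if (sj < 0) sj = 0; if (sj > W - 1) sj = W - 1;
      if (bilinear) {
        int i0 = (int)std::floor(si); if (i0 > H - 2) i0 = std::max(H - 2, 0);
        int j0 = (int)std::floor(sj); if (j0 > W - 2) j0 = std::max(W - 2, 0);
        const int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
        const double di = si - i0, dj = sj - j0;
        for (int c = 0; c < C; ++c)
          out(i, j, c) =
              (1 - di) * ((1 - dj) * img(i0, j0, c) + dj * img(i0, j1, c)) +
              di * ((1 - dj) * img(i1, j0, c) + dj * img(i1, j1, c));
      } else {
        const int ii = (int)std::lround(si), jj = (int)std::lround(sj);
        for (int c = 0; c < C; ++c) out(i, j, c) = img(ii, jj, c);
      }
    }
  return out;
}

static double ncc_at(const mat& ref, const mat& mov, const int r0, const int c0,
                     const int bh, const int bw, const int dy, const int dx,
                     const double refMean, const double refDen, bool& ok) {
  const int H = mov.n_rows, W = mov.n_cols;
  const int rr = r0 + dy, cc = c0 + dx;
  ok = false;
  if (rr < 0 || cc < 0 || rr + bh > H || cc + bw > W) return 0.0;
  double sb = 0, sbb = 0, sab = 0;
  for (int j = 0; j < bw; ++j)
    for (int i = 0; i < bh; ++i) {
      const double b = mov(rr + i, cc + j);
      sb += b; sbb += b * b; sab += ref(r0 + i, c0 + j) * b;
    }
  const double n = (double)bh * bw;
  const double movDen = sbb - sb * sb / n;
  if (movDen <= 1e-12 || refDen <= 1e-12) return 0.0;
  ok = true;
  return (sab - refMean * sb) / std::sqrt(refDen * movDen);
}

static double parafit(const double cm, const double c0, const double cp) {
  const double den = cm - 2.0 * c0 + cp;
  if (std::abs(den) < 1e-12) return 0.0;
  double d = 0.5 * (cm - cp) / den;
  if (d > 0.5) d = 0.5;
  if (d < -0.5) d = -0.5;
  return d;
}

// Search the moving image around block (r0, c0, bh, bw) of the reference for
// the NCC peak within +/- radius. Ties broken toward the smallest row offset,
// then the smallest column offset. Returns (dy, dx, peak, ok) with sub-pixel
// parabolic refinement along each axis.
// [[Rcpp::export]]
arma::vec sm_block_search(const arma::mat& ref, const arma::mat& mov,
                          const int r0, const int c0, const int bh,
                          const int bw, const int radius) {
  double sa = 0, saa = 0;
  for (int j = 0; j < bw; ++j)
    for (int i = 0; i < bh; ++i) {
      const double a = ref(r0 + i, c0 + j);
      sa += a; saa += a * a;
    }
  const double n = (double)bh * bw;
  const double refMean = sa / n;
  const double refDen = saa - sa * sa / n;
  arma::vec out(4, arma::fill::zeros);
  if (refDen <= 1e-12) return out;  // degenerate (constant) block
  const int S = 2 * radius + 1;
  mat cc(S, S); cc.fill(arma::datum::nan);
  double best = -2.0; int bdy = 0, bdx = 0;
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx) {
      bool ok;
      const double v =
          ncc_at(ref, mov, r0, c0, bh, bw, dy, dx, refMean, refDen, ok);
      if (!ok) continue;
      cc(dy + radius, dx + radius) = v;
      if (v > best + 1e-15) { best = v; bdy = dy; bdx = dx; }
    }
  if (best < -1.5) return out;  // nothing computable
  double ddy = 0, ddx = 0;
  const int iy = bdy + radius, ix = bdx + radius;
  if (iy > 0 && iy < S - 1 && std::isfinite(cc(iy - 1, ix)) &&
      std::isfinite(cc(iy + 1, ix)))
    ddy = parafit(cc(iy - 1, ix), cc(iy, ix), cc(iy + 1, ix));
  if (ix > 0 && ix < S - 1 && std::isfinite(cc(iy, ix - 1)) &&
      std::isfinite(cc(iy, ix + 1)))
    ddx = parafit(cc(iy, ix - 1), cc(iy, ix), cc(iy, ix + 1));
  out(0) = bdy + ddy; out(1) = bdx + ddx; out(2) = best; out(3) = 1;
  return out;
}

// NCC of two equal-shape blocks over their overlap for each candidate offset;
// used by blockShift() where no surrounding context exists.
// [[Rcpp::export]]
arma::vec sm_block_ncc_overlap(const arma::mat& a, const arma::mat& b,
                               const int radius) {
  const int H = a.n_rows, W = a.n_cols;
  const int S = 2 * radius + 1;
  mat cc(S, S); cc.fill(arma::datum::nan);
  double best = -2.0; int bdy = 0, bdx = 0;
  const int minH = std::max(4, H / 2), minW = std::max(4, W / 2);
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx) {
      // overlap of a(p) with b(p + d)
      const int r0a = std::max(0, -dy), c0a = std::max(0, -dx);
      const int r1a = std::min(H, H - dy), c1a = std::min(W, W - dx);
      const int oh = r1a - r0a, ow = c1a - c0a;
      if (oh < minH || ow < minW) continue;
      double saV = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
      for (int j = c0a; j < c1a; ++j)
        for (int i = r0a; i < r1a; ++i) {
          const double av = a(i, j), bv = b(i + dy, j + dx);
          saV += av; sb += bv; saa += av * av; sbb += bv * bv; sab += av * bv;
        }
      const double n = (double)oh * ow;
      const double da = saa - saV * saV / n, db = sbb - sb * sb / n;
      if (da <= 1e-12 || db <= 1e-12) continue;
      const double v = (sab - saV * sb / n) / std::sqrt(da * db);
      cc(dy + radius, dx + radius) = v;
      if (v > best + 1e-15) { best = v; bdy = dy; bdx = dx; }
    }
  arma::vec out(4, arma::fill::zeros);
  if (best < -1.5) return out;
  double ddy = 0, ddx = 0;
  const int iy = bdy + radius, ix = bdx + radius;
  if (iy > 0 && iy < S - 1 && std::isfinite(cc(iy - 1, ix)) &&
      std::isfinite(cc(iy + 1, ix)))
    ddy = parafit(cc(iy - 1, ix), cc(iy, ix), cc(iy + 1, ix));
  if (ix > 0 && ix < S - 1 && std::isfinite(cc(iy, ix - 1)) &&
      std::isfinite(cc(iy, ix + 1)))
    ddx = parafit(cc(iy, ix - 1), cc(iy, ix), cc(iy, ix + 1));
  out(0) = bdy + ddy; out(1) = bdx + ddx; out(2) = best; out(3) = 1;
  return out;
}

// Normalized cross-correlation of a template against every placement inside
// an image (valid placements only).
// [[Rcpp::export]]
arma::mat sm_template_ncc(const arma::mat& img, const arma::mat& templ) {
  const int H = img.n_rows, W = img.n_cols;
  const int th = templ.n_rows, tw = templ.n_cols;
  const int Ho = H - th + 1, Wo = W - tw + 1;
  mat out(Ho, Wo, arma::fill::zeros);
  const double n = (double)th * tw;
  const double st = arma::accu(templ);
  const double stt = arma::accu(templ % templ);
  const double tDen = stt - st * st / n;
  if (tDen <= 1e-12) return out;
  for (int c0 = 0; c0 < Wo; ++c0)
    for (int r0 = 0; r0 < Ho; ++r0) {
      double si = 0, sii = 0, sit = 0;
      for (int j = 0; j < tw; ++j)
        for (int i = 0; i < th; ++i) {
          const double v = img(r0 + i, c0 + j);
          si += v; sii += v * v; sit += v * templ(i, j);
        }
      const double iDen = sii - si * si / n;
      if (iDen <= 1e-12) continue;
      out(r0, c0) = (sit - si * st / n) / std::sqrt(iDen * tDen);
    }
  return out;
}

// Even-odd rasterization of polygons onto an h x w grid. Pixel (i, j)
// (1-based in R) has center (x, y) = (j - 0.5, i - 0.5); a pixel belongs to
// the last-listed polygon containing its center. Returns 0 where no polygon
// covers the pixel, else the 1-based polygon index.
// [[Rcpp::export]]
Rcpp::IntegerMatrix sm_rasterize(const int h, const int w,
                                 const Rcpp::List& polys) {
  Rcpp::IntegerMatrix mask(h, w);
  for (int k = 0; k < polys.size(); ++k) {
    Rcpp::NumericMatrix P(polys[k]);
    const int nv = P.nrow();
    double xmin = P(0, 0), xmax = P(0, 0), ymin = P(0, 1), ymax = P(0, 1);
    for (int v = 1; v < nv; ++v) {
      xmin = std::min(xmin, P(v, 0)); xmax = std::max(xmax, P(v, 0));
      ymin = std::min(ymin, P(v, 1)); ymax = std::max(ymax, P(v, 1));
    }
    const int j0 = std::max(0, (int)std::floor(xmin - 0.5));
    const int j1 = std::min(w - 1, (int)std::ceil(xmax + 0.5));
    const int i0 = std::max(0, (int)std::floor(ymin - 0.5));
    const int i1 = std::min(h - 1, (int)std::ceil(ymax + 0.5));
    for (int j = j0; j <= j1; ++j) {
      const double x = j + 0.5;
      for (int i = i0; i <= i1; ++i) {
        const double y = i + 0.5;
        bool inside = false;
        for (int v = 0, u = nv - 1; v < nv; u = v++) {
          const double xv = P(v, 0), yv = P(v, 1);
          const double xu = P(u, 0), yu = P(u, 1);
          if (((yv > y) != (yu > y)) &&
              (x < (xu - xv) * (y - yv) / (yu - yv) + xv))
            inside = !inside;
        }
        if (inside) mask(i, j) = k + 1;
      }
    }
  }
  return mask;
}
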