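#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Bicubic interpolation via prefiltered cubic B-splines (Unser's recursive
// prefilter + B-spline basis evaluation).  Interpolating (exact at integer
// coordinates), reproduces cubic polynomials, and has an order of magnitude
// less sub-pixel phase bias than cubic-convolution kernels -- the property
// that matters when frame-to-frame increments are summed.
// Coordinates are 1-based, x = column, y = row (origin top-left, x rightward,
// y downward).  Mirror boundaries in the prefilter, clamped access beyond.
// ---------------------------------------------------------------------------

static inline int iclamp(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// 0-based coefficient access, mirror boundaries (consistent with the
// prefilter, so border-pixel interpolation stays exact)
static inline int imirror(int v, int n) {
  if (v < 0) v = -v;
  if (v > n - 1) v = 2 * (n - 1) - v;
  return iclamp(v, 0, n - 1);
}

static inline double px(const double* img, int nr, int nc, int r, int c) {
  return img[imirror(r, nr) + (size_t)nr * imirror(c, nc)];
}

// cubic B-spline basis and its derivative (signed argument, support (-2, 2))
static inline double bsp3(double t) {
  t = std::fabs(t);
  if (t < 1.0) return (4.0 - 6.0 * t * t + 3.0 * t * t * t) / 6.0;
  if (t < 2.0) { double u = 2.0 - t; return u * u * u / 6.0; }
  return 0.0;
}

static inline double dbsp3(double t) {
  double s = (t < 0) ? -1.0 : 1.0;
  t = std::fabs(t);
  double g;
  if (t < 1.0)      g = t * (1.5 * t - 2.0);
  else if (t < 2.0) { double u = 2.0 - t; g = -0.5 * u * u; }
  else              g = 0.0;
  return s * g;
}

// in-place recursive prefilter of one line (stride access), mirror ends
static void prefilter_line(double* c, int n, size_t stride) {
  const double z = -0.26794919243112270647;   // sqrt(3) - 2
  const double gain = 6.0;
  if (n == 1) { c[0] *= 1.0; return; }
  for (int k = 0; k < n; ++k) c[(size_t)k * stride] *= gain;
  // causal init: truncated series over the mirrored signal
  int horizon = 42;                           // |z|^42 < 1e-24
  if (horizon > n) horizon = n;
  double sum = c[0], zk = z;
  for (int k = 1; k < horizon; ++k) {
    sum += zk * c[(size_t)k * stride];
    zk *= z;
  }
  c[0] = sum;
  for (int k = 1; k < n; ++k)
    c[(size_t)k * stride] += z * c[(size_t)(k - 1) * stride];
  // anti-causal init (mirror boundary)
  c[(size_t)(n - 1) * stride] =
    (z / (z * z - 1.0)) *
    (c[(size_t)(n - 1) * stride] + z * c[(size_t)(n - 2) * stride]);
  for (int k = n - 2; k >= 0; --k)
    c[(size_t)k * stride] =
      z * (c[(size_t)(k + 1) * stride] - c[(size_t)k * stride]);
}

static void prefilter_image(double* c, int nr, int nc) {
  for (int col = 0; col < nc; ++col)
    prefilter_line(c + (size_t)nr * col, nr, 1);
  for (int row = 0; row < nr; ++row)
    prefilter_line(c + row, nc, (size_t)nr);
}

// [[Rcpp::export]]
NumericMatrix cpp_bspline_coeffs(NumericMatrix img) {
  NumericMatrix out = clone(img);
  prefilter_image(out.begin(), out.nrow(), out.ncol());
  return out;
}

// evaluate the spline (coefficients `img`) at 1-based (x, y)
static double interp_one(const double* img, int nr, int nc, double x, double y) {
  double x0 = x - 1.0, y0 = y - 1.0;
  int ix = (int)std::floor(x0), iy = (int)std::floor(y0);
  double fx = x0 - ix, fy = y0 - iy;
  double wx[4], wy[4];
  for (int n = 0; n < 4; ++n) {
    wx[n] = bsp3(fx - (n - 1));
    wy[n] = bsp3(fy - (n - 1));
  }
  double acc = 0.0;
  for (int m = 0; m < 4; ++m) {
    double rowacc = 0.0;
    for (int n = 0; n < 4; ++n)
      rowacc += wx[n] * px(img, nr, nc, iy - 1 + m, ix - 1 + n);
    acc += wy[m] * rowacc;
  }
  return acc;
}

static void grad_one(const double* img, int nr, int nc, double x, double y,
                     double& gx, double& gy) {
  double x0 = x - 1.0, y0 = y - 1.0;
  int ix = (int)std::floor(x0), iy = (int)std::floor(y0);
  double fx = x0 - ix, fy = y0 - iy;
  double wx[4], wy[4], dx[4], dy[4];
  for (int n = 0; n < 4; ++n) {
    wx[n] = bsp3(fx - (n - 1));
    wy[n] = bsp3(fy - (n - 1));
    dx[n] = dbsp3(fx - (n - 1));
    dy[n] = dbsp3(fy - (n - 1));
  }
  gx = 0.0; gy = 0.0;
  for (int m = 0; m < 4; ++m) {
    double rw = 0.0, rd = 0.0;
    for (int n = 0; n < 4; ++n) {
      double v = px(img, nr, nc, iy - 1 + m, ix - 1 + n);
      rw += wx[n] * v;
      rd += dx[n] * v;
    }
    gx += wy[m] * rd;
    gy += dy[m] * rw;
  }
}

// [[Rcpp::export]]
NumericVector cpp_interp_image(NumericMatrix img, NumericVector x, NumericVector y) {
  NumericMatrix cf = cpp_bspline_coeffs(img);
  int nr = img.nrow(), nc = img.ncol();
  R_xlen_t n = x.size();
  NumericVector out(n);
  const double* p = cf.begin();
  for (R_xlen_t i = 0; i < n; ++i) out[i] = interp_one(p, nr, nc, x[i], y[i]);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_grad_image(NumericMatrix img, NumericVector x, NumericVector y) {
  NumericMatrix cf = cpp_bspline_coeffs(img);
  int nr = img.nrow(), nc = img.ncol();
  R_xlen_t n = x.size();
  NumericMatrix out(n, 2);
  const double* p = cf.begin();
  double gx, gy;
  for (R_xlen_t i = 0; i < n; ++i) {
    grad_one(p, nr, nc, x[i], y[i], gx, gy);
    out(i, 0) = gx; out(i, 1) = gy;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Speckle rendering utilities
// ---------------------------------------------------------------------------

// Anti-aliased dark dots on a light background (min-composited).
// [[Rcpp::export]]
NumericMatrix cpp_render_dots(int nrow, int ncol,
                              NumericVector cx, NumericVector cy,
                              NumericVector radius,
                              double fg, double bg) {
  NumericMatrix img(nrow, ncol);
  std::fill(img.begin(), img.end(), bg);
  R_xlen_t nd = cx.size();
  for (R_xlen_t d = 0; d < nd; ++d) {
    double xc = cx[d], yc = cy[d], r = radius[d];
    int c0 = iclamp((int)std::floor(xc - r - 2.0) - 1, 0, ncol - 1);
    int c1 = iclamp((int)std::ceil(xc + r + 2.0) - 1, 0, ncol - 1);
    int r0 = iclamp((int)std::floor(yc - r - 2.0) - 1, 0, nrow - 1);
    int r1 = iclamp((int)std::ceil(yc + r + 2.0) - 1, 0, nrow - 1);
    for (int cc = c0; cc <= c1; ++cc) {
      double dx = (cc + 1) - xc;
      for (int rr = r0; rr <= r1; ++rr) {
        double dy = (rr + 1) - yc;
        double dist = std::sqrt(dx * dx + dy * dy);
        double cov = 0.5 + (r - dist);
        if (cov <= 0.0) continue;
        if (cov > 1.0) cov = 1.0;
        double val = bg + (fg - bg) * cov;
        if (val < img(rr, cc)) img(rr, cc) = val;
      }
    }
  }
  return img;
}

// Separable Gaussian blur with replicated borders.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (double& v : k) v /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)       // horizontal pass
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i)
        acc += k[i + rad] * img(r, iclamp(c + i, 0, nc - 1));
      tmp(r, c) = acc;
    }
  for (int c = 0; c < nc; ++c)       // vertical pass
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i)
        acc += k[i + rad] * tmp(iclamp(r + i, 0, nr - 1), c);
      out(r, c) = acc;
    }
  return out;
}

// Warp an image by a 3x3 homography H mapping OUTPUT pixel (x, y, 1) to
// SOURCE pixel coordinates; bicubic B-spline sampling, clamped borders.
// [[Rcpp::export]]
NumericMatrix cpp_warp_homography(NumericMatrix src, NumericMatrix H,
                                  int out_nrow, int out_ncol) {
  int nr = src.nrow(), nc = src.ncol();
  NumericMatrix cf = cpp_bspline_coeffs(src);
  const double* p = cf.begin();
  NumericMatrix out(out_nrow, out_ncol);
  double h11 = H(0,0), h12 = H(0,1), h13 = H(0,2);
  double h21 = H(1,0), h22 = H(1,1), h23 = H(1,2);
  double h31 = H(2,0), h32 = H(2,1), h33 = H(2,2);
  for (int c = 0; c < out_ncol; ++c) {
    double x = c + 1;
    for (int r = 0; r < out_nrow; ++r) {
      double y = r + 1;
      double w  = h31 * x + h32 * y + h33;
      double xs = (h11 * x + h12 * y + h13) / w;
      double ys = (h21 * x + h22 * y + h23) / w;
      out(r, c) = interp_one(p, nr, nc, xs, ys);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Subset correlation
// ---------------------------------------------------------------------------

// Integer-displacement ZNCC search in a (2*range+1)^2 window around the
// (rounded) seed (u0, v0).  The reference subset is extracted once; both
// subsets use direct (integer) pixel access for speed.
// [[Rcpp::export]]
NumericVector cpp_zncc_search(NumericMatrix ref, NumericMatrix cur,
                              double cx, double cy, int half,
                              double u0, double v0, int range) {
  int nr = ref.nrow(), nc = ref.ncol();
  const double* rp = ref.begin();
  const double* cp = cur.begin();
  int side = 2 * half + 1, n = side * side;
  int icx = (int)std::lround(cx), icy = (int)std::lround(cy);
  int su = (int)std::lround(cx + u0) - icx;   // integer seed displacement
  int sv = (int)std::lround(cy + v0) - icy;
  if (icx - half < 1 || icx + half > nc || icy - half < 1 || icy + half > nr)
    return NumericVector::create(u0, v0, -2.0);

  std::vector<double> T(n);
  double tsum = 0.0;
  {
    int k = 0;
    for (int j = -half; j <= half; ++j)
      for (int i = -half; i <= half; ++i, ++k) {
        T[k] = px(rp, nr, nc, icy - 1 + j, icx - 1 + i);
        tsum += T[k];
      }
  }
  double tmean = tsum / n, tvar = 0.0;
  for (int k = 0; k < n; ++k) { T[k] -= tmean; tvar += T[k] * T[k]; }
  if (tvar <= 1e-12) return NumericVector::create(u0, v0, -2.0);
  double dT = std::sqrt(tvar);

  double best = -2.0; int bu = 0, bv = 0;
  for (int dv = -range; dv <= range; ++dv) {
    int oy = icy + sv + dv;
    if (oy - half < 1 || oy + half > nr) continue;
    for (int du = -range; du <= range; ++du) {
      int ox = icx + su + du;
      if (ox - half < 1 || ox + half > nc) continue;
      double sc = 0, scc = 0, src_ = 0;
      int k = 0;
      for (int j = -half; j <= half; ++j)
        for (int i = -half; i <= half; ++i, ++k) {
          double b = cp[(size_t)(oy - 1 + j) + (size_t)nr * (ox - 1 + i)];
          sc += b; scc += b * b; src_ += T[k] * b;
        }
      double vb = scc - sc * sc / n;
      if (vb <= 1e-12) continue;
      double z = src_ / (dT * std::sqrt(vb));
      if (z > best) { best = z; bu = su + du; bv = sv + dv; }
    }
  }
  return NumericVector::create((double)bu + (icx - cx),
                               (double)bv + (icy - cy), best);
}

// Inverse-compositional Gauss-Newton minimisation of the ZNSSD criterion
// with a first-order (affine) subset shape function.
// p = (u, v, ux, uy, vx, vy); warp of subset-local (dx, dy):
//   x' = cx + u + (1+ux) dx + uy dy
//   y' = cy + v + vx dx + (1+vy) dy
// Returns c(u, v, ux, uy, vx, vy, zncc, converged, iterations, code)
// code: 0 ok, 1 out-of-bounds, 2 flat subset, 3 no convergence, 4 diverged
// When `prefiltered` is true the matrices are B-spline coefficient arrays
// from cpp_bspline_coeffs (the batch path); otherwise raw images are
// prefiltered here.
// [[Rcpp::export]]
NumericVector cpp_icgn(NumericMatrix refm, NumericMatrix curm,
                       double cx, double cy, int half,
                       NumericVector p0,
                       double tol = 1e-4, int max_iter = 50,
                       bool prefiltered = false) {
  NumericMatrix refc = prefiltered ? refm : cpp_bspline_coeffs(refm);
  NumericMatrix curc = prefiltered ? curm : cpp_bspline_coeffs(curm);
  const double* ref = refc.begin();
  const double* cur = curc.begin();
  int nr = refm.nrow(), nc = refm.ncol();
  int side = 2 * half + 1, n = side * side;

  NumericVector out(10);
  auto fail = [&](int code, double u, double v) {
    out[0] = u; out[1] = v;
    out[6] = NA_REAL; out[7] = 0; out[8] = 0; out[9] = code;
    return out;
  };

  if (cx - half < 2 || cx + half > nc - 1 || cy - half < 2 || cy + half > nr - 1)
    return fail(1, p0[0], p0[1]);

  // reference subset and steepest-descent images
  std::vector<double> T(n), Jm(6 * (size_t)n);
  double tsum = 0.0;
  {
    int k = 0;
    for (int j = -half; j <= half; ++j)
      for (int i = -half; i <= half; ++i, ++k) {
        double x = cx + i, y = cy + j;
        T[k] = interp_one(ref, nr, nc, x, y);
        tsum += T[k];
        double gx, gy;
        grad_one(ref, nr, nc, x, y, gx, gy);
        Jm[k]             = gx;          // d/du
        Jm[k + (size_t)n]     = gy;      // d/dv
        Jm[k + 2 * (size_t)n] = gx * i;  // d/dux
        Jm[k + 3 * (size_t)n] = gx * j;  // d/duy
        Jm[k + 4 * (size_t)n] = gy * i;  // d/dvx
        Jm[k + 5 * (size_t)n] = gy * j;  // d/dvy
      }
  }
  double tmean = tsum / n, tvar = 0.0;
  for (int k = 0; k < n; ++k) { T[k] -= tmean; tvar += T[k] * T[k]; }
  double dT = std::sqrt(tvar);
  if (dT < 1e-10) return fail(2, p0[0], p0[1]);

  // Hessian (6x6) and its Cholesky factorisation
  double H[36] = {0};
  for (int a = 0; a < 6; ++a)
    for (int b = a; b < 6; ++b) {
      double s = 0.0;
      const double* ja = &Jm[a * (size_t)n];
      const double* jb = &Jm[b * (size_t)n];
      for (int k = 0; k < n; ++k) s += ja[k] * jb[k];
      H[a * 6 + b] = H[b * 6 + a] = s;
    }
  double L[36] = {0};
  for (int a = 0; a < 6; ++a) {
    for (int b = 0; b <= a; ++b) {
      double s = H[a * 6 + b];
      for (int c2 = 0; c2 < b; ++c2) s -= L[a * 6 + c2] * L[b * 6 + c2];
      if (a == b) {
        if (s <= 1e-12) return fail(2, p0[0], p0[1]);
        L[a * 6 + a] = std::sqrt(s);
      } else {
        L[a * 6 + b] = s / L[b * 6 + b];
      }
    }
  }
  auto chol_solve = [&](const double* b, double* x) {
    double y[6];
    for (int a = 0; a < 6; ++a) {
      double s = b[a];
      for (int c2 = 0; c2 < a; ++c2) s -= L[a * 6 + c2] * y[c2];
      y[a] = s / L[a * 6 + a];
    }
    for (int a = 5; a >= 0; --a) {
      double s = y[a];
      for (int c2 = a + 1; c2 < 6; ++c2) s -= L[c2 * 6 + a] * x[c2];
      x[a] = s / L[a * 6 + a];
    }
  };

  // current warp as 2x3 (affine part A, translation t), acting on (dx, dy)
  double A11 = 1 + p0[2], A12 = p0[3], A21 = p0[4], A22 = 1 + p0[5];
  double tx = p0[0], ty = p0[1];

  std::vector<double> I(n);
  int iter = 0;
  bool converged = false;
  for (iter = 1; iter <= max_iter; ++iter) {
    // sample current subset
    double isum = 0.0;
    {
      int k = 0;
      for (int j = -half; j <= half; ++j)
        for (int i = -half; i <= half; ++i, ++k) {
          double x = cx + tx + A11 * i + A12 * j;
          double y = cy + ty + A21 * i + A22 * j;
          if (x < 2 || x > nc - 1 || y < 2 || y > nr - 1)
            return fail(1, tx, ty);
          I[k] = interp_one(cur, nr, nc, x, y);
          isum += I[k];
        }
    }
    double imean = isum / n, ivar = 0.0;
    for (int k = 0; k < n; ++k) { I[k] -= imean; ivar += I[k] * I[k]; }
    double dI = std::sqrt(ivar);
    if (dI < 1e-10) return fail(2, tx, ty);

    double ratio = dT / dI;
    double b[6] = {0};
    for (int a = 0; a < 6; ++a) {
      const double* ja = &Jm[a * (size_t)n];
      double s = 0.0;
      for (int k = 0; k < n; ++k) s += ja[k] * (ratio * I[k] - T[k]);
      b[a] = s;
    }
    double dp[6];
    chol_solve(b, dp);

    // inverse-compositional update: W <- W o W(dp)^{-1}
    double B11 = 1 + dp[2], B12 = dp[3], B21 = dp[4], B22 = 1 + dp[5];
    double det = B11 * B22 - B12 * B21;
    if (std::fabs(det) < 1e-12) return fail(4, tx, ty);
    double C11 =  B22 / det, C12 = -B12 / det;
    double C21 = -B21 / det, C22 =  B11 / det;
    double cu = -(C11 * dp[0] + C12 * dp[1]);
    double cv = -(C21 * dp[0] + C22 * dp[1]);
    double nA11 = A11 * C11 + A12 * C21, nA12 = A11 * C12 + A12 * C22;
    double nA21 = A21 * C11 + A22 * C21, nA22 = A21 * C12 + A22 * C22;
    double ntx = A11 * cu + A12 * cv + tx;
    double nty = A21 * cu + A22 * cv + ty;
    A11 = nA11; A12 = nA12; A21 = nA21; A22 = nA22; tx = ntx; ty = nty;

    if (std::fabs(tx) > nc || std::fabs(ty) > nr) return fail(4, tx, ty);

    double upd = std::sqrt(dp[0] * dp[0] + dp[1] * dp[1] +
                           (double)half * half *
                           (dp[2] * dp[2] + dp[3] * dp[3] +
                            dp[4] * dp[4] + dp[5] * dp[5]));
    if (upd < tol) { converged = true; break; }
  }

  // ZNCC at the converged warp
  double isum = 0.0, icc = 0.0, ivar = 0.0;
  {
    int k = 0;
    for (int j = -half; j <= half; ++j)
      for (int i = -half; i <= half; ++i, ++k) {
        double x = cx + tx + A11 * i + A12 * j;
        double y = cy + ty + A21 * i + A22 * j;
        if (x < 2 || x > nc - 1 || y < 2 || y > nr - 1)
          return fail(1, tx, ty);
        I[k] = interp_one(cur, nr, nc, x, y);
        isum += I[k];
      }
    double imean = isum / n;
    for (k = 0; k < n; ++k) {
      double d = I[k] - imean;
      icc += T[k] * d;       // T already centred
      ivar += d * d;
    }
  }
  double zncc = (ivar > 1e-12) ? icc / (dT * std::sqrt(ivar)) : 0.0;

  out[0] = tx; out[1] = ty;
  out[2] = A11 - 1; out[3] = A12; out[4] = A21; out[5] = A22 - 1;
  out[6] = zncc;
  out[7] = converged ? 1 : 0;
  out[8] = iter > max_iter ? max_iter : iter;
  out[9] = converged ? 0 : 3;
  return out;
}

// Track a set of subsets between two frames.  Each point is seeded with
// (u0, v0); if IC-GN fails, or converges to a match with ZNCC below
// `zncc_accept` (a likely false lock on a neighbouring speckle), an
// integer ZNCC search (+- search_range px) around the seed re-seeds one
// retry and the better converged match is kept.
// Returns an n x 10 matrix with cpp_icgn's columns.
// [[Rcpp::export]]
NumericMatrix cpp_track_points(NumericMatrix ref, NumericMatrix cur,
                               NumericVector cx, NumericVector cy, int half,
                               NumericVector u0, NumericVector v0,
                               int search_range = 10,
                               double tol = 1e-4, int max_iter = 50,
                               double zncc_accept = 0.8) {
  R_xlen_t np = cx.size();
  NumericMatrix out(np, 10);
  NumericVector p(6);
  NumericMatrix refc = cpp_bspline_coeffs(ref);
  NumericMatrix curc = cpp_bspline_coeffs(cur);
  for (R_xlen_t k = 0; k < np; ++k) {
    p[0] = u0[k]; p[1] = v0[k];
    p[2] = p[3] = p[4] = p[5] = 0.0;
    NumericVector r = cpp_icgn(refc, curc, cx[k], cy[k], half, p,
                               tol, max_iter, true);
    bool ok = r[7] == 1;
    if ((!ok || r[6] < zncc_accept) && search_range > 0) {
      NumericVector s = cpp_zncc_search(ref, cur, cx[k], cy[k], half,
                                        u0[k], v0[k], search_range);
      if (s[2] > 0.2) {
        p[0] = s[0]; p[1] = s[1];
        NumericVector r2 = cpp_icgn(refc, curc, cx[k], cy[k], half, p,
                                    tol, max_iter, true);
        if (r2[7] == 1 && (!ok || r2[6] > r[6])) r = r2;
      }
    }
    for (int j = 0; j < 10; ++j) out(k, j) = r[j];
  }
  return out;
}
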