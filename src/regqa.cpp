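#include <Rcpp.h>
#include <unordered_map>
#include <functional>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Cubic B-spline blending weights at fractional offset s in [0,1), for the
// four control points floor(t)-1 .. floor(t)+2.
static inline void bw(double s, double w[4]) {
  double s2 = s * s, s3 = s2 * s;
  w[0] = (1.0 - 3.0 * s + 3.0 * s2 - s3) / 6.0;
  w[1] = (3.0 * s3 - 6.0 * s2 + 4.0) / 6.0;
  w[2] = (-3.0 * s3 + 3.0 * s2 + 3.0 * s + 1.0) / 6.0;
  w[3] = s3 / 6.0;
}

// Derivatives of the four weights with respect to t (per control index).
static inline void bwd(double s, double d[4]) {
  double s2 = s * s;
  d[0] = -(1.0 - 2.0 * s + s2) / 2.0;
  d[1] = (3.0 * s2 - 4.0 * s) / 2.0;
  d[2] = (-3.0 * s2 + 2.0 * s + 1.0) / 2.0;
  d[3] = s2 / 2.0;
}

struct Grid3 {
  const double *cx, *cy, *cz;   // coefficient components, each m0*m1*m2
  int m0, m1, m2;
  double o0, o1, o2;            // control grid origin (mm)
  double h0, h1, h2;            // control spacing (mm)
};

// Evaluate displacement at one physical point.  Returns false when the point
// lies outside the cubic support of the control grid.
static inline bool disp_one(const Grid3 &g, double px, double py, double pz,
                            double out[3]) {
  double t0 = (px - g.o0) / g.h0;
  double t1 = (py - g.o1) / g.h1;
  double t2 = (pz - g.o2) / g.h2;
  int l0 = (int)std::floor(t0), l1 = (int)std::floor(t1), l2 = (int)std::floor(t2);
  if (l0 < 1 || l0 + 2 > g.m0 - 1 || l1 < 1 || l1 + 2 > g.m1 - 1 ||
      l2 < 1 || l2 + 2 > g.m2 - 1)
    return false;
  double wx[4], wy[4], wz[4];
  bw(t0 - l0, wx); bw(t1 - l1, wy); bw(t2 - l2, wz);
  double ux = 0.0, uy = 0.0, uz = 0.0;
  for (int c = 0; c < 4; ++c) {
    int kc = l2 - 1 + c;
    for (int b = 0; b < 4; ++b) {
      int kb = l1 - 1 + b;
      double wyz = wy[b] * wz[c];
      size_t base = (size_t)(kc * g.m1 + kb) * g.m0 + (l0 - 1);
      for (int a = 0; a < 4; ++a) {
        double w = wx[a] * wyz;
        ux += w * g.cx[base + a];
        uy += w * g.cy[base + a];
        uz += w * g.cz[base + a];
      }
    }
  }
  out[0] = ux; out[1] = uy; out[2] = uz;
  return true;
}

static Grid3 make_grid(NumericVector cx, NumericVector cy, NumericVector cz,
                       NumericVector gorigin, NumericVector gspacing) {
  IntegerVector d = cx.attr("dim");
  Grid3 g;
  g.cx = REAL(cx); g.cy = REAL(cy); g.cz = REAL(cz);
  g.m0 = d[0]; g.m1 = d[1]; g.m2 = d[2];
  g.o0 = gorigin[0]; g.o1 = gorigin[1]; g.o2 = gorigin[2];
  g.h0 = gspacing[0]; g.h1 = gspacing[1]; g.h2 = gspacing[2];
  return g;
}

// [[Rcpp::export]]
NumericMatrix cpp_bspline_disp(NumericVector cx, NumericVector cy,
                               NumericVector cz, NumericVector gorigin,
                               NumericVector gspacing, NumericMatrix pts) {
  Grid3 g = make_grid(cx, cy, cz, gorigin, gspacing);
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  double u[3];
  for (int i = 0; i < n; ++i) {
    if (!disp_one(g, pts(i, 0), pts(i, 1), pts(i, 2), u))
      stop("point %d is outside the transform support", i + 1);
    out(i, 0) = u[0]; out(i, 1) = u[1]; out(i, 2) = u[2];
  }
  return out;
}

// Fixed-point inversion of the forward map x -> x + u(x): given y, solve
// for x with y = x + u(x).  Points whose iteration leaves the support or
// fails to reach `tol` within `maxit` are flagged.
// [[Rcpp::export]]
List cpp_bspline_invert(NumericVector cx, NumericVector cy, NumericVector cz,
                        NumericVector gorigin, NumericVector gspacing,
                        NumericMatrix pts, double tol, int maxit) {
  Grid3 g = make_grid(cx, cy, cz, gorigin, gspacing);
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  LogicalVector failed(n);
  double u[3];
  for (int i = 0; i < n; ++i) {
    double y0 = pts(i, 0), y1 = pts(i, 1), y2 = pts(i, 2);
    double x0 = y0, x1 = y1, x2 = y2;
    bool ok = false;
    for (int it = 0; it < maxit; ++it) {
      if (!disp_one(g, x0, x1, x2, u)) { ok = false; break; }
      double n0 = y0 - u[0], n1 = y1 - u[1], n2 = y2 - u[2];
      double dd = std::sqrt((n0 - x0) * (n0 - x0) + (n1 - x1) * (n1 - x1) +
                            (n2 - x2) * (n2 - x2));
      x0 = n0; x1 = n1; x2 = n2;
      if (dd < tol) { ok = true; break; }
    }
    out(i, 0) = x0; out(i, 1) = x1; out(i, 2) = x2;
    failed[i] = !ok;
  }
  return List::create(_["points"] = out, _["failed"] = failed);
}

// Trilinear interpolation of a volume at physical points (voxel-center
// convention: voxel (i,j,k), 0-based here, sits at origin + idx*spacing).
// [[Rcpp::export]]
NumericVector cpp_resample_trilinear(NumericVector data, IntegerVector dims,
                                     NumericVector spacing,
                                     NumericVector origin, NumericMatrix pts,
                                     double pad) {
  int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  const double *v = REAL(data);
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double f0 = (pts(i, 0) - origin[0]) / spacing[0];
    double f1 = (pts(i, 1) - origin[1]) / spacing[1];
    double f2 = (pts(i, 2) - origin[2]) / spacing[2];
    int i0 = (int)std::floor(f0), i1 = (int)std::floor(f1), i2 = (int)std::floor(f2);
    double a0 = f0 - i0, a1 = f1 - i1, a2 = f2 - i2;
    double acc = 0.0;
    bool any = false;
    for (int c = 0; c < 2; ++c) {
      int k2 = i2 + c;
      double w2 = c ? a2 : 1.0 - a2;
      if (w2 == 0.0) continue;
      for (int b = 0; b < 2; ++b) {
        int k1 = i1 + b;
        double w12 = (b ? a1 : 1.0 - a1) * w2;
        if (w12 == 0.0) continue;
        for (int a = 0; a < 2; ++a) {
          int k0 = i0 + a;
          double w = (a ? a0 : 1.0 - a0) * w12;
          if (w == 0.0) continue;
          if (k0 < 0 || k0 >= n0 || k1 < 0 || k1 >= n1 || k2 < 0 || k2 >= n2) {
            acc += w * pad;
          } else {
            acc += w * v[(size_t)(k2 * n1 + k1) * n0 + k0];
            any = true;
          }
        }
      }
    }
    out[i] = any ? acc : pad;
  }
  return out;
}

// Exact Eq.-style RMS displacement over every voxel center of a frame:
// returns (3D RMS, in-plane RMS, max |u|).
// [[Rcpp::export]]
NumericVector cpp_de_dense(NumericVector cx, NumericVector cy,
                           NumericVector cz, NumericVector gorigin,
                           NumericVector gspacing, IntegerVector dims,
                           NumericVector spacing, NumericVector origin) {
  Grid3 g = make_grid(cx, cy, cz, gorigin, gspacing);
  int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  double u[3];
  double s3 = 0.0, sax = 0.0, mx = 0.0;
  for (int k = 0; k < n2; ++k) {
    double pz = origin[2] + k * spacing[2];
    for (int j = 0; j < n1; ++j) {
      double py = origin[1] + j * spacing[1];
      for (int i = 0; i < n0; ++i) {
        double px = origin[0] + i * spacing[0];
        if (!disp_one(g, px, py, pz, u))
          stop("frame voxel outside transform support");
        double ax = u[0] * u[0] + u[1] * u[1];
        double m = ax + u[2] * u[2];
        s3 += m; sax += ax;
        if (m > mx) mx = m;
      }
    }
  }
  double N = (double)n0 * n1 * n2;
  return NumericVector::create(std::sqrt(s3 / N), std::sqrt(sax / N),
                               std::sqrt(mx));
}

// 26-connected component labelling of a sparse voxel list.
// coords: n x 3 matrix of 0-based voxel indices.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerMatrix coords, IntegerVector dims) {
  int n = coords.nrow();
  long long n0 = dims[0], n1 = dims[1];
  std::unordered_map<long long, int> pos;
  pos.reserve(n * 2);
  for (int i = 0; i < n; ++i) {
    long long code = ((long long)coords(i, 2) * n1 + coords(i, 1)) * n0 +
                     coords(i, 0);
    pos[code] = i;
  }
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int i = 0; i < n; ++i) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          long long code = ((long long)(coords(i, 2) + dz) * n1 +
                            (coords(i, 1) + dy)) * n0 + (coords(i, 0) + dx);
          auto it = pos.find(code);
          if (it != pos.end()) {
            int ra = find(i), rb = find(it->second);
            if (ra != rb) parent[rb] = ra;
          }
        }
  }
  // canonical labels in first-appearance (lexicographic storage) order
  std::unordered_map<int, int> lab;
  IntegerVector out(n);
  int next = 1;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    auto it = lab.find(r);
    if (it == lab.end()) { lab[r] = next; out[i] = next; ++next; }
    else out[i] = it->second;
  }
  return out;
}

// For each row of `a`, the minimum Euclidean distance to any row of `b`.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix a, NumericMatrix b) {
  int n = a.nrow(), m = b.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double x = a(i, 0), y = a(i, 1), z = a(i, 2);
    for (int j = 0; j < m; ++j) {
      double d0 = x - b(j, 0), d1 = y - b(j, 1), d2 = z - b(j, 2);
      double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

static void conv_axis(std::vector<double> &buf, const double *src, double *dst,
                      int n0, int n1, int n2, int axis,
                      const std::vector<double> &kern) {
  int r = ((int)kern.size() - 1) / 2;
  int len = axis == 0 ? n0 : (axis == 1 ? n1 : n2);
  (void)buf;
  for (int k = 0; k < n2; ++k)
    for (int j = 0; j < n1; ++j)
      for (int i = 0; i < n0; ++i) {
        double acc = 0.0, wsum = 0.0;
        for (int t = -r; t <= r; ++t) {
          int ii = i, jj = j, kk = k;
          if (axis == 0) ii += t; else if (axis == 1) jj += t; else kk += t;
          int idx = axis == 0 ? ii : (axis == 1 ? jj : kk);
          if (idx < 0 || idx >= len) continue;  // renormalised at edges
          double w = kern[t + r];
          acc += w * src[(size_t)(kk * n1 + jj) * n0 + ii];
          wsum += w;
        }
        dst[(size_t)(k * n1 + j) * n0 + i] = wsum > 0 ? acc / wsum : 0.0;
      }
}

// Separable Gaussian blur with edge renormalisation; sigma in voxels per axis.
// [[Rcpp::export]]
NumericVector cpp_blur_gaussian(NumericVector data, IntegerVector dims,
                                NumericVector sigma_vox) {
  int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  size_t n = (size_t)n0 * n1 * n2;
  std::vector<double> a(REAL(data), REAL(data) + n), b(n);
  std::vector<double> scratch;
  double *src = a.data(), *dst = b.data();
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> kern(2 * r + 1);
    for (int t = -r; t <= r; ++t) kern[t + r] = std::exp(-0.5 * t * t / (s * s));
    conv_axis(scratch, src, dst, n0, n1, n2, axis, kern);
    std::swap(src, dst);
  }
  NumericVector out(n);
  std::copy(src, src + n, REAL(out));
  out.attr("dim") = dims;
  return out;
}

// One evaluation of the SSD objective and its gradient with respect to the
// B-spline coefficients, for the pull-back warp model  W(y) = S(y + u(y)).
// Image gradients of S are taken analytically from the trilinear interpolant.
// [[Rcpp::export]]
List cpp_ffd_ssd_grad(NumericVector src, NumericVector tgt, IntegerVector dims,
                      NumericVector spacing, NumericVector origin,
                      NumericVector cx, NumericVector cy, NumericVector cz,
                      NumericVector gorigin, NumericVector gspacing,
                      bool want_grad) {
  Grid3 g = make_grid(cx, cy, cz, gorigin, gspacing);
  int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  const double *S = REAL(src), *T = REAL(tgt);
  size_t ncoef = (size_t)g.m0 * g.m1 * g.m2;
  NumericVector gxv(want_grad ? ncoef : 0), gyv(want_grad ? ncoef : 0),
      gzv(want_grad ? ncoef : 0);
  double ssd = 0.0;
  double u[3];
  for (int k = 0; k < n2; ++k) {
    double pz = origin[2] + k * spacing[2];
    for (int j = 0; j < n1; ++j) {
      double py = origin[1] + j * spacing[1];
      for (int i = 0; i < n0; ++i) {
        double px = origin[0] + i * spacing[0];
        if (!disp_one(g, px, py, pz, u)) continue;
        double q0 = px + u[0], q1 = py + u[1], q2 = pz + u[2];
        double f0 = (q0 - origin[0]) / spacing[0];
        double f1 = (q1 - origin[1]) / spacing[1];
        double f2 = (q2 - origin[2]) / spacing[2];
        // edge-clamped sampling keeps the objective continuous in the
        // coefficients; clamped axes contribute zero image gradient
        bool cl0 = false, cl1 = false, cl2 = false;
        if (f0 < 0) { f0 = 0; cl0 = true; }
        if (f0 > n0 - 1) { f0 = n0 - 1; cl0 = true; }
        if (f1 < 0) { f1 = 0; cl1 = true; }
        if (f1 > n1 - 1) { f1 = n1 - 1; cl1 = true; }
        if (f2 < 0) { f2 = 0; cl2 = true; }
        if (f2 > n2 - 1) { f2 = n2 - 1; cl2 = true; }
        int i0 = (int)std::floor(f0), i1 = (int)std::floor(f1),
            i2 = (int)std::floor(f2);
        if (i0 > n0 - 2) i0 = n0 - 2;
        if (i1 > n1 - 2) i1 = n1 - 2;
        if (i2 > n2 - 2) i2 = n2 - 2;
        double a0 = f0 - i0, a1 = f1 - i1, a2 = f2 - i2;
        double val = 0.0, gx = 0.0, gy = 0.0, gz = 0.0;
        for (int c = 0; c < 2; ++c) {
          double w2 = c ? a2 : 1.0 - a2;
          for (int b = 0; b < 2; ++b) {
            double w1 = b ? a1 : 1.0 - a1;
            for (int a = 0; a < 2; ++a) {
              double w0 = a ? a0 : 1.0 - a0;
              double w = w0 * w1 * w2;
              int x0 = i0 + a, x1 = i1 + b, x2 = i2 + c;
              double sv = S[(size_t)(x2 * n1 + x1) * n0 + x0];
              val += w * sv;
              if (!want_grad || w == 0.0) continue;
              // central-difference image gradient at the corner (one-sided
              // at faces): smooth in the coefficients, no lattice kinks
              int xp = x0 + 1 > n0 - 1 ? n0 - 1 : x0 + 1;
              int xm = x0 - 1 < 0 ? 0 : x0 - 1;
              gx += w * (S[(size_t)(x2 * n1 + x1) * n0 + xp] -
                         S[(size_t)(x2 * n1 + x1) * n0 + xm]) /
                    ((xp - xm) * spacing[0]);
              int yp = x1 + 1 > n1 - 1 ? n1 - 1 : x1 + 1;
              int ym = x1 - 1 < 0 ? 0 : x1 - 1;
              gy += w * (S[(size_t)(x2 * n1 + yp) * n0 + x0] -
                         S[(size_t)(x2 * n1 + ym) * n0 + x0]) /
                    ((yp - ym) * spacing[1]);
              int zp = x2 + 1 > n2 - 1 ? n2 - 1 : x2 + 1;
              int zm = x2 - 1 < 0 ? 0 : x2 - 1;
              gz += w * (S[(size_t)(zp * n1 + x1) * n0 + x0] -
                         S[(size_t)(zm * n1 + x1) * n0 + x0]) /
                    ((zp - zm) * spacing[2]);
            }
          }
        }
        double r = val - T[(size_t)(k * n1 + j) * n0 + i];
        ssd += r * r;
        if (!want_grad) continue;
        if (cl0) gx = 0.0;
        if (cl1) gy = 0.0;
        if (cl2) gz = 0.0;
        double t0 = (px - g.o0) / g.h0, t1 = (py - g.o1) / g.h1,
               t2 = (pz - g.o2) / g.h2;
        int l0 = (int)std::floor(t0), l1 = (int)std::floor(t1),
            l2 = (int)std::floor(t2);
        double wx[4], wy[4], wz[4];
        bw(t0 - l0, wx); bw(t1 - l1, wy); bw(t2 - l2, wz);
        for (int c = 0; c < 4; ++c)
          for (int b = 0; b < 4; ++b) {
            double wyz = wy[b] * wz[c];
            size_t base =
                (size_t)((l2 - 1 + c) * g.m1 + (l1 - 1 + b)) * g.m0 + (l0 - 1);
            for (int a = 0; a < 4; ++a) {
              double w = 2.0 * r * wx[a] * wyz;
              gxv[base + a] += w * gx;
              gyv[base + a] += w * gy;
              gzv[base + a] += w * gz;
            }
          }
      }
    }
  }
  List out = List::create(_["ssd"] = ssd);
  if (want_grad) {
    IntegerVector gd = IntegerVector::create(g.m0, g.m1, g.m2);
    gxv.attr("dim") = gd; gyv.attr("dim") = gd; gzv.attr("dim") = gd;
    out["gx"] = gxv; out["gy"] = gyv; out["gz"] = gzv;
  }
  return out;
}
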