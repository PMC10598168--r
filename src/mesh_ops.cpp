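#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Moeller-Trumbore ray/triangle intersection. Returns t >= 0 or -1.
static inline double ray_tri(const double *o, const double *d,
                             const double *v0, const double *v1,
                             const double *v2) {
  const double eps = 1e-12;
  double e1[3], e2[3], p[3], tv[3], q[3];
  for (int k = 0; k < 3; ++k) {
    e1[k] = v1[k] - v0[k];
    e2[k] = v2[k] - v0[k];
  }
  p[0] = d[1] * e2[2] - d[2] * e2[1];
  p[1] = d[2] * e2[0] - d[0] * e2[2];
  p[2] = d[0] * e2[1] - d[1] * e2[0];
  double det = e1[0] * p[0] + e1[1] * p[1] + e1[2] * p[2];
  if (std::fabs(det) < eps) return -1.0;
  double inv = 1.0 / det;
  for (int k = 0; k < 3; ++k) tv[k] = o[k] - v0[k];
  double u = (tv[0] * p[0] + tv[1] * p[1] + tv[2] * p[2]) * inv;
  if (u < -1e-9 || u > 1.0 + 1e-9) return -1.0;
  q[0] = tv[1] * e1[2] - tv[2] * e1[1];
  q[1] = tv[2] * e1[0] - tv[0] * e1[2];
  q[2] = tv[0] * e1[1] - tv[1] * e1[0];
  double v = (d[0] * q[0] + d[1] * q[1] + d[2] * q[2]) * inv;
  if (v < -1e-9 || u + v > 1.0 + 1e-9) return -1.0;
  double t = (e2[0] * q[0] + e2[1] * q[1] + e2[2] * q[2]) * inv;
  return t;
}

// First positive ray-mesh hit per ray, within (tmin, tmax]. NA if none.
// [[Rcpp::export]]
NumericVector cpp_ray_mesh(NumericMatrix origins, NumericMatrix dirs,
                           NumericMatrix V, IntegerMatrix F,
                           double tmax, double tmin = 1e-7) {
  int nr = origins.nrow(), nf = F.nrow();
  NumericVector out(nr, NA_REAL);
  std::vector<double> vx(V.nrow() * 3);
  for (int i = 0; i < V.nrow(); ++i)
    for (int k = 0; k < 3; ++k) vx[3 * i + k] = V(i, k);
  for (int r = 0; r < nr; ++r) {
    double o[3] = { origins(r, 0), origins(r, 1), origins(r, 2) };
    double d[3] = { dirs(r, 0), dirs(r, 1), dirs(r, 2) };
    if (!std::isfinite(d[0]) || !std::isfinite(d[1]) || !std::isfinite(d[2]))
      continue;
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double t = ray_tri(o, d, &vx[3 * (F(f, 0) - 1)],
                         &vx[3 * (F(f, 1) - 1)], &vx[3 * (F(f, 2) - 1)]);
      if (t > tmin && t <= tmax && t < best) best = t;
    }
    if (std::isfinite(best)) out[r] = best;
  }
  return out;
}

// Voxelize a watertight mesh by z-column crossing parity.
// Returns integer vector of length nx*ny*nz (x fastest, column-major).
// [[Rcpp::export]]
IntegerVector cpp_voxelize(NumericMatrix V, IntegerMatrix F,
                           int nx, int ny, int nz, double sp,
                           double ox, double oy, double oz) {
  IntegerVector occ(nx * ny * nz, 0);
  std::vector<std::vector<double>> cross((size_t)nx * ny);
  int nf = F.nrow();
  // tiny irrational offsets avoid rays passing exactly through edges
  const double jx = 1.2345e-6 * sp, jy = 2.7183e-6 * sp;
  for (int f = 0; f < nf; ++f) {
    double v0[3] = { V(F(f,0)-1,0), V(F(f,0)-1,1), V(F(f,0)-1,2) };
    double v1[3] = { V(F(f,1)-1,0), V(F(f,1)-1,1), V(F(f,1)-1,2) };
    double v2[3] = { V(F(f,2)-1,0), V(F(f,2)-1,1), V(F(f,2)-1,2) };
    double xmin = std::min({v0[0], v1[0], v2[0]}), xmax = std::max({v0[0], v1[0], v2[0]});
    double ymin = std::min({v0[1], v1[1], v2[1]}), ymax = std::max({v0[1], v1[1], v2[1]});
    int i0 = std::max(0, (int)std::ceil((xmin - jx - ox) / sp));
    int i1 = std::min(nx - 1, (int)std::floor((xmax - jx - ox) / sp));
    int j0 = std::max(0, (int)std::ceil((ymin - jy - oy) / sp));
    int j1 = std::min(ny - 1, (int)std::floor((ymax - jy - oy) / sp));
    double d[3] = { 0.0, 0.0, 1.0 };
    for (int j = j0; j <= j1; ++j) {
      for (int i = i0; i <= i1; ++i) {
        double o[3] = { ox + i * sp + jx, oy + j * sp + jy, oz - 1.0 };
        double t = ray_tri(o, d, v0, v1, v2);
        if (t > 0) cross[(size_t)j * nx + i].push_back(oz - 1.0 + t);
      }
    }
  }
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      std::vector<double> &cz = cross[(size_t)j * nx + i];
      if (cz.size() < 2) continue;
      std::sort(cz.begin(), cz.end());
      for (size_t p = 0; p + 1 < cz.size(); p += 2) {
        // half-open [z_in, z_out): unbiased expected sample count per span
        int k0 = std::max(0, (int)std::ceil((cz[p] - oz) / sp));
        int k1 = std::min(nz - 1, (int)std::ceil((cz[p + 1] - oz) / sp) - 1);
        for (int k = k0; k <= k1; ++k)
          occ[(size_t)k * nx * ny + (size_t)j * nx + i] = 1;
      }
    }
  }
  return occ;
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// Closest point on a triangle (Ericson, Real-Time Collision Detection).
static void closest_on_tri(const double *p, const double *a, const double *b,
                           const double *c, double *out, double *bary) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k]; ac[k] = c[k] - a[k]; ap[k] = p[k] - a[k];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) {
    for (int k = 0; k < 3; ++k) out[k] = a[k];
    bary[0] = 1; bary[1] = 0; bary[2] = 0; return;
  }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) {
    for (int k = 0; k < 3; ++k) out[k] = b[k];
    bary[0] = 0; bary[1] = 1; bary[2] = 0; return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = clamp01(d1 / (d1 - d3));
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    bary[0] = 1 - v; bary[1] = v; bary[2] = 0; return;
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) {
    for (int k = 0; k < 3; ++k) out[k] = c[k];
    bary[0] = 0; bary[1] = 0; bary[2] = 1; return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = clamp01(d2 / (d2 - d6));
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    bary[0] = 1 - w; bary[1] = 0; bary[2] = w; return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = clamp01((d4 - d3) / ((d4 - d3) + (d5 - d6)));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    bary[0] = 0; bary[1] = 1 - w; bary[2] = w; return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
  bary[0] = 1 - v - w; bary[1] = v; bary[2] = w;
}

// Closest point on mesh per query point.
// Returns n x 8: face (1-based), px, py, pz, dist, b0, b1, b2.
// [[Rcpp::export]]
NumericMatrix cpp_closest_point(NumericMatrix P, NumericMatrix V,
                                IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  NumericMatrix out(np, 8);
  for (int i = 0; i < np; ++i) {
    double p[3] = { P(i, 0), P(i, 1), P(i, 2) };
    double best = R_PosInf, bq[3] = {0, 0, 0}, bb[3] = {0, 0, 0};
    int bf = -1;
    for (int f = 0; f < nf; ++f) {
      double a[3] = { V(F(f,0)-1,0), V(F(f,0)-1,1), V(F(f,0)-1,2) };
      double b[3] = { V(F(f,1)-1,0), V(F(f,1)-1,1), V(F(f,1)-1,2) };
      double c[3] = { V(F(f,2)-1,0), V(F(f,2)-1,1), V(F(f,2)-1,2) };
      double q[3], ba[3];
      closest_on_tri(p, a, b, c, q, ba);
      double d2 = (p[0]-q[0])*(p[0]-q[0]) + (p[1]-q[1])*(p[1]-q[1]) +
                  (p[2]-q[2])*(p[2]-q[2]);
      if (d2 < best) {
        best = d2; bf = f;
        for (int k = 0; k < 3; ++k) { bq[k] = q[k]; bb[k] = ba[k]; }
      }
    }
    out(i, 0) = bf + 1;
    out(i, 1) = bq[0]; out(i, 2) = bq[1]; out(i, 3) = bq[2];
    out(i, 4) = std::sqrt(best);
    out(i, 5) = bb[0]; out(i, 6) = bb[1]; out(i, 7) = bb[2];
  }
  return out;
}
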