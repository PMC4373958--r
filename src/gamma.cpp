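#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// clamped trilinear interpolation of a 3D field stored x-fastest
static inline double trilin(const double* v, const int* n,
                            const double* origin, const double* spacing,
                            double px, double py, double pz) {
  double f[3] = {(px - origin[0]) / spacing[0] - 0.5,
                 (py - origin[1]) / spacing[1] - 0.5,
                 (pz - origin[2]) / spacing[2] - 0.5};
  int i0[3], i1[3];
  double t[3];
  for (int a = 0; a < 3; ++a) {
    double fl = std::floor(f[a]);
    int lo = (int)fl;
    int hi_lo = n[a] - 2;
    if (hi_lo < 0) hi_lo = 0;
    if (lo < 0) lo = 0;
    if (lo > hi_lo) lo = hi_lo;
    double tt = f[a] - lo;
    if (tt < 0) tt = 0;
    if (tt > 1) tt = 1;
    i0[a] = lo;
    i1[a] = lo + 1 < n[a] ? lo + 1 : n[a] - 1;
    t[a] = tt;
  }
  const int nx = n[0];
  const long nxy = (long)n[0] * n[1];
  #define V(i, j, k) v[(i) + nx * (long)(j) + nxy * (long)(k)]
  double c00 = V(i0[0], i0[1], i0[2]) * (1 - t[0]) + V(i1[0], i0[1], i0[2]) * t[0];
  double c10 = V(i0[0], i1[1], i0[2]) * (1 - t[0]) + V(i1[0], i1[1], i0[2]) * t[0];
  double c01 = V(i0[0], i0[1], i1[2]) * (1 - t[0]) + V(i1[0], i0[1], i1[2]) * t[0];
  double c11 = V(i0[0], i1[1], i1[2]) * (1 - t[0]) + V(i1[0], i1[1], i1[2]) * t[0];
  #undef V
  double c0 = c00 * (1 - t[1]) + c10 * t[1];
  double c1 = c01 * (1 - t[1]) + c11 * t[1];
  return c0 * (1 - t[2]) + c1 * t[2];
}

// Gamma index for 3D evaluation points against a reference grid.
// offsets are sorted by distance; dist_term holds (|offset| / dta)^2, which
// allows an early exit once the distance term alone exceeds the running
// minimum.
// [[Rcpp::export]]
NumericVector gamma_points_cpp(NumericVector ref, IntegerVector dim,
                               NumericVector origin, NumericVector spacing,
                               NumericMatrix pos, NumericVector eval_dose,
                               NumericMatrix offsets, NumericVector dist_term,
                               double tol_abs) {
  const int np = pos.nrow(), nm = offsets.nrow();
  NumericVector out(np);
  const double* v = REAL(ref);
  const int* n = INTEGER(dim);
  const double* org = REAL(origin);
  const double* sp = REAL(spacing);
  for (int p = 0; p < np; ++p) {
    const double px = pos(p, 0), py = pos(p, 1), pz = pos(p, 2);
    const double de = eval_dose[p];
    double best = R_PosInf;
    for (int m = 0; m < nm; ++m) {
      const double dt = dist_term[m];
      if (dt >= best) break;  // offsets sorted: no later offset can improve
      double dr = trilin(v, n, org, sp, px + offsets(m, 0),
                         py + offsets(m, 1), pz + offsets(m, 2));
      double dd = (dr - de) / tol_abs;
      double g2 = dt + dd * dd;
      if (g2 < best) best = g2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

// Gamma index for points on the unwrapped detector cylinder surface.
// Evaluation points are (s, z) with s the arc length; 2D offsets (ds, dz)
// move along the surface, and the reference 3D grid is interpolated at the
// corresponding cylinder point x = R sin(s/R), y = R cos(s/R).
// [[Rcpp::export]]
NumericVector gamma_cylinder_cpp(NumericVector ref, IntegerVector dim,
                                 NumericVector origin, NumericVector spacing,
                                 double radius, NumericVector s,
                                 NumericVector z, NumericVector eval_dose,
                                 NumericMatrix offsets,
                                 NumericVector dist_term, double tol_abs) {
  const int np = s.size(), nm = offsets.nrow();
  NumericVector out(np);
  const double* v = REAL(ref);
  const int* n = INTEGER(dim);
  const double* org = REAL(origin);
  const double* sp = REAL(spacing);
  for (int p = 0; p < np; ++p) {
    const double de = eval_dose[p];
    double best = R_PosInf;
    for (int m = 0; m < nm; ++m) {
      const double dt = dist_term[m];
      if (dt >= best) break;
      double phi = (s[p] + offsets(m, 0)) / radius;
      double dr = trilin(v, n, org, sp, radius * std::sin(phi),
                         radius * std::cos(phi), z[p] + offsets(m, 1));
      double dd = (dr - de) / tol_abs;
      double g2 = dt + dd * dd;
      if (g2 < best) best = g2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
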