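#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Moller-Trumbore ray/triangle intersection. Returns t > t_eps on hit,
// -1 otherwise. Shared semantics with the R brute-force oracle.
static inline double mt_hit(const double *o, const double *d,
                            const double *a, const double *b,
                            const double *c, double t_eps) {
  double e1[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double e2[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double p[3] = {d[1] * e2[2] - d[2] * e2[1],
                 d[2] * e2[0] - d[0] * e2[2],
                 d[0] * e2[1] - d[1] * e2[0]};
  double det = e1[0] * p[0] + e1[1] * p[1] + e1[2] * p[2];
  if (std::fabs(det) < 1e-12) return -1.0;
  double inv = 1.0 / det;
  double s[3] = {o[0] - a[0], o[1] - a[1], o[2] - a[2]};
  double u = (s[0] * p[0] + s[1] * p[1] + s[2] * p[2]) * inv;
  if (u < 0.0 || u > 1.0) return -1.0;
  double q[3] = {s[1] * e1[2] - s[2] * e1[1],
                 s[2] * e1[0] - s[0] * e1[2],
                 s[0] * e1[1] - s[1] * e1[0]};
  double v = (d[0] * q[0] + d[1] * q[1] + d[2] * q[2]) * inv;
  if (v < 0.0 || u + v > 1.0) return -1.0;
  double t = (e2[0] * q[0] + e2[1] * q[1] + e2[2] * q[2]) * inv;
  if (t <= t_eps) return -1.0;
  return t;
}

// Occlusion along a single beam direction, accelerated by a uniform 2D grid
// in the plane perpendicular to the beam (orthographic beam projection):
// each triangle is binned by its projected bounding box; each query point
// projects to a single cell whose candidate list is then tested exactly.
// [[Rcpp::export]]
LogicalVector cpp_occluded(NumericMatrix origins, NumericVector dir,
                           NumericMatrix v1, NumericMatrix v2,
                           NumericMatrix v3, IntegerVector self,
                           double cell = 5.0, double t_eps = 1e-3) {
  const int n = origins.nrow(), m = v1.nrow();
  LogicalVector out(n);
  if (m == 0) return out;
  double d[3] = {dir[0], dir[1], dir[2]};
  double dn = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  for (int k = 0; k < 3; ++k) d[k] /= dn;
  // orthonormal basis (u, w) of the projection plane
  double u[3], w[3];
  if (std::fabs(d[2]) < 0.9) { u[0] = -d[1]; u[1] = d[0]; u[2] = 0.0; }
  else { u[0] = 1.0; u[1] = 0.0; u[2] = 0.0; }
  double un = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
  for (int k = 0; k < 3; ++k) u[k] /= un;
  // make u orthogonal to d, then w = d x u
  double du = u[0]*d[0] + u[1]*d[1] + u[2]*d[2];
  for (int k = 0; k < 3; ++k) u[k] -= du * d[k];
  un = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
  for (int k = 0; k < 3; ++k) u[k] /= un;
  w[0] = d[1]*u[2] - d[2]*u[1];
  w[1] = d[2]*u[0] - d[0]*u[2];
  w[2] = d[0]*u[1] - d[1]*u[0];

  std::vector<double> pu(3 * m), pw(3 * m);
  double umin = R_PosInf, umax = R_NegInf, wmin = R_PosInf, wmax = R_NegInf;
  for (int i = 0; i < m; ++i) {
    const double *vs[3] = {&v1(i, 0), &v2(i, 0), &v3(i, 0)};
    // NumericMatrix is column-major; take explicit copies
    double a[3] = {v1(i,0), v1(i,1), v1(i,2)};
    double b[3] = {v2(i,0), v2(i,1), v2(i,2)};
    double cvt[3] = {v3(i,0), v3(i,1), v3(i,2)};
    (void)vs;
    const double *tri[3] = {a, b, cvt};
    for (int k = 0; k < 3; ++k) {
      double uu = tri[k][0]*u[0] + tri[k][1]*u[1] + tri[k][2]*u[2];
      double ww = tri[k][0]*w[0] + tri[k][1]*w[1] + tri[k][2]*w[2];
      pu[3*i + k] = uu; pw[3*i + k] = ww;
      if (uu < umin) umin = uu; if (uu > umax) umax = uu;
      if (ww < wmin) wmin = ww; if (ww > wmax) wmax = ww;
    }
  }
  int nu = std::max(1, (int)((umax - umin) / cell) + 1);
  int nw = std::max(1, (int)((wmax - wmin) / cell) + 1);
  // cap grid memory for pathological extents
  while ((double)nu * (double)nw > 4e6) { nu = (nu + 1) / 2; nw = (nw + 1) / 2; }
  double cu = (umax - umin) / nu, cw = (wmax - wmin) / nw;
  if (cu <= 0) cu = 1.0;
  if (cw <= 0) cw = 1.0;
  std::vector<std::vector<int> > bins((size_t)nu * nw);
  for (int i = 0; i < m; ++i) {
    double tu0 = std::min(pu[3*i], std::min(pu[3*i+1], pu[3*i+2]));
    double tu1 = std::max(pu[3*i], std::max(pu[3*i+1], pu[3*i+2]));
    double tw0 = std::min(pw[3*i], std::min(pw[3*i+1], pw[3*i+2]));
    double tw1 = std::max(pw[3*i], std::max(pw[3*i+1], pw[3*i+2]));
    int iu0 = std::max(0, std::min(nu - 1, (int)((tu0 - umin) / cu)));
    int iu1 = std::max(0, std::min(nu - 1, (int)((tu1 - umin) / cu)));
    int iw0 = std::max(0, std::min(nw - 1, (int)((tw0 - wmin) / cw)));
    int iw1 = std::max(0, std::min(nw - 1, (int)((tw1 - wmin) / cw)));
    for (int a = iu0; a <= iu1; ++a)
      for (int b = iw0; b <= iw1; ++b)
        bins[(size_t)a * nw + b].push_back(i);
  }
  for (int q = 0; q < n; ++q) {
    double o[3] = {origins(q, 0), origins(q, 1), origins(q, 2)};
    double ou = o[0]*u[0] + o[1]*u[1] + o[2]*u[2];
    double ow = o[0]*w[0] + o[1]*w[1] + o[2]*w[2];
    int iu = (int)((ou - umin) / cu), iw = (int)((ow - wmin) / cw);
    if (iu < 0 || iu >= nu || iw < 0 || iw >= nw) { out[q] = false; continue; }
    const std::vector<int> &cand = bins[(size_t)iu * nw + iw];
    bool hit = false;
    int selfid = self.size() > q ? self[q] : -1;
    for (size_t ci = 0; ci < cand.size() && !hit; ++ci) {
      int i = cand[ci];
      if (i == selfid) continue;
      double a[3] = {v1(i,0), v1(i,1), v1(i,2)};
      double b[3] = {v2(i,0), v2(i,1), v2(i,2)};
      double c2[3] = {v3(i,0), v3(i,1), v3(i,2)};
      if (mt_hit(o, d, a, b, c2, t_eps) > 0) hit = true;
    }
    out[q] = hit;
  }
  return out;
}
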