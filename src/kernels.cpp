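// Compiled kernels for the quasistatic forward solver and geometry queries.
// All positions handed to these routines are in METERS; the R layer owns the
// mm <-> m conversion. Charges are stored as g = rho/eps0 so eps0 never
// appears in the system.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double MU0_OVER_4PI = 1e-7; // mu0 / (4 pi)

// E_p(r) = -(mu0/4pi) * dIdt * sum_k m_k x (r - p_k) / |r - p_k|^3
// [[Rcpp::export]]
arma::mat cpp_dipole_field(const arma::mat& pos, const arma::mat& mom,
                           const arma::mat& pts, double dIdt) {
  const arma::uword nd = pos.n_rows, np = pts.n_rows;
  arma::mat E(np, 3, arma::fill::zeros);
  for (arma::uword i = 0; i < np; ++i) {
    double rx = pts(i, 0), ry = pts(i, 1), rz = pts(i, 2);
    double ex = 0, ey = 0, ez = 0;
    for (arma::uword k = 0; k < nd; ++k) {
      double dx = rx - pos(k, 0), dy = ry - pos(k, 1), dz = rz - pos(k, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      double ir3 = 1.0 / (r2 * std::sqrt(r2));
      // m x d
      ex += (mom(k, 1) * dz - mom(k, 2) * dy) * ir3;
      ey += (mom(k, 2) * dx - mom(k, 0) * dz) * ir3;
      ez += (mom(k, 0) * dy - mom(k, 1) * dx) * ir3;
    }
    E(i, 0) = -MU0_OVER_4PI * dIdt * ex;
    E(i, 1) = -MU0_OVER_4PI * dIdt * ey;
    E(i, 2) = -MU0_OVER_4PI * dIdt * ez;
  }
  return E;
}

// Signed solid angle of triangle (q1,q2,q3) seen from r (van Oosterom &
// Strackee). Positive when r lies on the side the right-hand (CCW) normal
// points AWAY from; the caller fixes the convention.
static inline double solid_angle(const double* q1, const double* q2,
                                 const double* q3, const double* r) {
  double a[3], b[3], c[3];
  for (int j = 0; j < 3; ++j) {
    a[j] = q1[j] - r[j];
    b[j] = q2[j] - r[j];
    c[j] = q3[j] - r[j];
  }
  double la = std::sqrt(a[0]*a[0]+a[1]*a[1]+a[2]*a[2]);
  double lb = std::sqrt(b[0]*b[0]+b[1]*b[1]+b[2]*b[2]);
  double lc = std::sqrt(c[0]*c[0]+c[1]*c[1]+c[2]*c[2]);
  double triple = a[0]*(b[1]*c[2]-b[2]*c[1])
                - a[1]*(b[0]*c[2]-b[2]*c[0])
                + a[2]*(b[0]*c[1]-b[1]*c[0]);
  double den = la*lb*lc + (a[0]*b[0]+a[1]*b[1]+a[2]*b[2])*lc
             + (b[0]*c[0]+b[1]*c[1]+b[2]*c[2])*la
             + (a[0]*c[0]+a[1]*c[1]+a[2]*c[2])*lb;
  return 2.0 * std::atan2(triple, den);
}

// Exact I_T(r) = \int_T (r - r')/|r - r'|^3 dA' for a flat triangle with
// vertices (q1,q2,q3) ordered CCW about the unit normal nrm.
// Decomposition: normal part n * Omega_signed (Omega_signed -> 2*pi*sign(h)
// for the full plane), in-plane part from per-edge log terms.
static inline void tri_kernel_exact(const double* q1, const double* q2,
                                    const double* q3, const double* nrm,
                                    const double* r, double* out) {
  // normal part: van Oosterom value is negative on the +normal side for a
  // CCW triangle, so flip sign.
  double omega = -solid_angle(q1, q2, q3, r);
  out[0] = nrm[0] * omega;
  out[1] = nrm[1] * omega;
  out[2] = nrm[2] * omega;
  const double* va[3] = {q1, q2, q3};
  const double* vb[3] = {q2, q3, q1};
  for (int e = 0; e < 3; ++e) {
    double s[3], d1[3], d2[3];
    double L = 0;
    for (int j = 0; j < 3; ++j) {
      s[j] = vb[e][j] - va[e][j];
      L += s[j] * s[j];
    }
    L = std::sqrt(L);
    for (int j = 0; j < 3; ++j) s[j] /= L;
    double Rm = 0, Rp = 0, lm = 0, lp = 0;
    for (int j = 0; j < 3; ++j) {
      d1[j] = va[e][j] - r[j];
      d2[j] = vb[e][j] - r[j];
      Rm += d1[j] * d1[j];
      Rp += d2[j] * d2[j];
      lm += d1[j] * s[j];
      lp += d2[j] * s[j];
    }
    Rm = std::sqrt(Rm);
    Rp = std::sqrt(Rp);
    double lg = std::log((Rp + lp) / (Rm + lm));
    // m_hat = s x n (outward in-plane edge normal for CCW ordering)
    double mh[3] = {s[1]*nrm[2]-s[2]*nrm[1],
                    s[2]*nrm[0]-s[0]*nrm[2],
                    s[0]*nrm[1]-s[1]*nrm[0]};
    out[0] += mh[0] * lg;
    out[1] += mh[1] * lg;
    out[2] += mh[2] * lg;
  }
}

// E-field (per unit g, times 1/(4 pi) applied here) of the surface charge:
// far facets use the centroid point kernel A_k (r-c_k)/(4 pi |r-c_k|^3),
// facets with |r-c_k| < near_mult*sqrt(A_k) use the exact triangle integral.
// [[Rcpp::export]]
arma::mat cpp_charge_field(const arma::mat& v1, const arma::mat& v2,
                           const arma::mat& v3, const arma::mat& cen,
                           const arma::mat& nrm, const arma::vec& area,
                           const arma::vec& g, const arma::mat& pts,
                           double near_mult) {
  const arma::uword nf = cen.n_rows, np = pts.n_rows;
  arma::vec near2(nf);
  for (arma::uword k = 0; k < nf; ++k) {
    double t = near_mult * std::sqrt(area[k]);
    near2[k] = t * t;
  }
  const double inv4pi = 1.0 / (4.0 * M_PI);
  arma::mat E(np, 3, arma::fill::zeros);
  for (arma::uword i = 0; i < np; ++i) {
    double r[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double ex = 0, ey = 0, ez = 0;
    for (arma::uword k = 0; k < nf; ++k) {
      double dx = r[0] - cen(k, 0), dy = r[1] - cen(k, 1), dz = r[2] - cen(k, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > near2[k]) {
        double w = g[k] * area[k] / (r2 * std::sqrt(r2));
        ex += w * dx; ey += w * dy; ez += w * dz;
      } else {
        double q1[3] = {v1(k,0), v1(k,1), v1(k,2)};
        double q2[3] = {v2(k,0), v2(k,1), v2(k,2)};
        double q3[3] = {v3(k,0), v3(k,1), v3(k,2)};
        double nn[3] = {nrm(k,0), nrm(k,1), nrm(k,2)};
        double I[3];
        tri_kernel_exact(q1, q2, q3, nn, r, I);
        ex += g[k] * I[0]; ey += g[k] * I[1]; ez += g[k] * I[2];
      }
    }
    E(i, 0) = inv4pi * ex;
    E(i, 1) = inv4pi * ey;
    E(i, 2) = inv4pi * ez;
  }
  return E;
}

// Collocation operator of the charge integral equation:
//   A[m,m] = diag_coef[m]  ( = (sig_in + sig_out) / (2 (sig_in - sig_out)) )
//   A[m,k] = - n_m . <K_k>_m,  k != m
// with K_k the same far/near kernel as cpp_charge_field (per unit g), and
// <.>_m the average over the test points of facet m (rows of tp whose
// 0-based tidx equals m; passing the centroids with one point per facet
// reproduces plain centroid collocation). Averaging the test functional
// over the facet markedly improves accuracy for closely spaced coarse
// interfaces at no memory cost.
// [[Rcpp::export]]
arma::mat cpp_assemble(const arma::mat& v1, const arma::mat& v2,
                       const arma::mat& v3, const arma::mat& cen,
                       const arma::mat& nrm, const arma::vec& area,
                       const arma::vec& diag_coef, double near_mult,
                       const arma::mat& tp, const arma::ivec& tidx) {
  const arma::uword nf = cen.n_rows, np = tp.n_rows;
  arma::vec near2(nf);
  for (arma::uword k = 0; k < nf; ++k) {
    double t = near_mult * std::sqrt(area[k]);
    near2[k] = t * t;
  }
  const double inv4pi = 1.0 / (4.0 * M_PI);
  // group test points by their facet
  std::vector< std::vector<arma::uword> > pts_of(nf);
  for (arma::uword p = 0; p < np; ++p)
    pts_of[(arma::uword)tidx[p]].push_back(p);
  arma::mat A(nf, nf);
  arma::vec rowbuf(nf);
  for (arma::uword m = 0; m < nf; ++m) {
    rowbuf.zeros();
    double nm[3] = {nrm(m, 0), nrm(m, 1), nrm(m, 2)};
    const std::vector<arma::uword>& pl = pts_of[m];
    for (size_t pi = 0; pi < pl.size(); ++pi) {
      arma::uword p = pl[pi];
      double r[3] = {tp(p, 0), tp(p, 1), tp(p, 2)};
      for (arma::uword k = 0; k < nf; ++k) {
        if (k == m) continue;
        double dx = r[0] - cen(k, 0), dy = r[1] - cen(k, 1), dz = r[2] - cen(k, 2);
        double r2 = dx * dx + dy * dy + dz * dz;
        double dot;
        if (r2 > near2[k]) {
          double w = area[k] / (r2 * std::sqrt(r2));
          dot = w * (nm[0] * dx + nm[1] * dy + nm[2] * dz);
        } else {
          double q1[3] = {v1(k,0), v1(k,1), v1(k,2)};
          double q2[3] = {v2(k,0), v2(k,1), v2(k,2)};
          double q3[3] = {v3(k,0), v3(k,1), v3(k,2)};
          double nn[3] = {nrm(k,0), nrm(k,1), nrm(k,2)};
          double I[3];
          tri_kernel_exact(q1, q2, q3, nn, r, I);
          dot = nm[0] * I[0] + nm[1] * I[1] + nm[2] * I[2];
        }
        rowbuf[k] += -inv4pi * dot;
      }
    }
    double inv_cnt = 1.0 / (double)pl.size();
    for (arma::uword k = 0; k < nf; ++k) A(m, k) = rowbuf[k] * inv_cnt;
    A(m, m) = diag_coef[m];
  }
  return A;
}

// Closest point on triangle (Ericson, Real-Time Collision Detection).
static inline void closest_on_tri(const double* p, const double* a,
                                  const double* b, const double* c,
                                  double* out) {
  double ab[3], ac[3], ap[3];
  for (int j = 0; j < 3; ++j) {
    ab[j] = b[j] - a[j]; ac[j] = c[j] - a[j]; ap[j] = p[j] - a[j];
  }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int j=0;j<3;++j) out[j]=a[j]; return; }
  double bp[3];
  for (int j = 0; j < 3; ++j) bp[j] = p[j] - b[j];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int j=0;j<3;++j) out[j]=b[j]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int j=0;j<3;++j) out[j] = a[j] + v*ab[j];
    return;
  }
  double cp[3];
  for (int j = 0; j < 3; ++j) cp[j] = p[j] - c[j];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int j=0;j<3;++j) out[j]=c[j]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int j=0;j<3;++j) out[j] = a[j] + w*ac[j];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int j=0;j<3;++j) out[j] = b[j] + w*(c[j]-b[j]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int j=0;j<3;++j) out[j] = a[j] + ab[j]*v + ac[j]*w;
}

// Min point-to-triangle distance from each point to a triangle soup.
// Returns a list: dist (n), tri (1-based index, n), closest (n x 3).
// [[Rcpp::export]]
List cpp_point_tri_dist(const arma::mat& pts, const arma::mat& v1,
                        const arma::mat& v2, const arma::mat& v3) {
  const arma::uword np = pts.n_rows, nf = v1.n_rows;
  arma::vec dmin(np);
  arma::ivec imin(np);
  arma::mat cl(np, 3);
  for (arma::uword i = 0; i < np; ++i) {
    double p[3] = {pts(i,0), pts(i,1), pts(i,2)};
    double best = R_PosInf; arma::uword bk = 0;
    double bc[3] = {0,0,0};
    for (arma::uword k = 0; k < nf; ++k) {
      double a[3] = {v1(k,0), v1(k,1), v1(k,2)};
      double b[3] = {v2(k,0), v2(k,1), v2(k,2)};
      double c[3] = {v3(k,0), v3(k,1), v3(k,2)};
      double q[3];
      closest_on_tri(p, a, b, c, q);
      double d2 = (p[0]-q[0])*(p[0]-q[0]) + (p[1]-q[1])*(p[1]-q[1])
                + (p[2]-q[2])*(p[2]-q[2]);
      if (d2 < best) { best = d2; bk = k; bc[0]=q[0]; bc[1]=q[1]; bc[2]=q[2]; }
    }
    dmin[i] = std::sqrt(best);
    imin[i] = (int)bk + 1;
    cl(i,0) = bc[0]; cl(i,1) = bc[1]; cl(i,2) = bc[2];
  }
  return List::create(_["dist"] = dmin, _["tri"] = imin, _["closest"] = cl);
}

// For each row of a: nearest row of b (brute force). Returns list with
// dist (n) and idx (1-based, n).
// [[Rcpp::export]]
List cpp_nearest_point(const arma::mat& a, const arma::mat& b) {
  const arma::uword na = a.n_rows, nb = b.n_rows;
  arma::vec dmin(na);
  arma::ivec imin(na);
  for (arma::uword i = 0; i < na; ++i) {
    double x = a(i,0), y = a(i,1), z = a(i,2);
    double best = R_PosInf; arma::uword bk = 0;
    for (arma::uword k = 0; k < nb; ++k) {
      double dx = x - b(k,0), dy = y - b(k,1), dz = z - b(k,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) { best = d2; bk = k; }
    }
    dmin[i] = std::sqrt(best);
    imin[i] = (int)bk + 1;
  }
  return List::create(_["dist"] = dmin, _["idx"] = imin);
}

// Exact triangle kernel exposed for the quadrature-oracle test.
// [[Rcpp::export]]
arma::rowvec cpp_tri_kernel(const arma::rowvec& q1, const arma::rowvec& q2,
                            const arma::rowvec& q3, const arma::rowvec& nrm,
                            const arma::rowvec& r) {
  double a[3] = {q1[0], q1[1], q1[2]};
  double b[3] = {q2[0], q2[1], q2[2]};
  double c[3] = {q3[0], q3[1], q3[2]};
  double n[3] = {nrm[0], nrm[1], nrm[2]};
  double p[3] = {r[0], r[1], r[2]};
  double I[3];
  tri_kernel_exact(a, b, c, n, p, I);
  return arma::rowvec({I[0], I[1], I[2]});
}
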