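#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Accumulate the radiological path (areal density, g/cm^2) along the segment
// p0 -> p1 through a voxelized density volume (g/cm^3, spacing in mm).
// Exact voxel traversal (Amanatides-Woo stepping of the Siddon parametrization);
// additive over split points and symmetric in the endpoints up to roundoff.
static double traverse_areal(const double *dens, const int *dim,
                             const double *org, const double *sp,
                             const double *p0, const double *p1) {
  double lo[3], hi[3], d[3];
  double L2 = 0.0;
  for (int a = 0; a < 3; ++a) {
    lo[a] = org[a] - 0.5 * sp[a];
    hi[a] = lo[a] + dim[a] * sp[a];
    d[a] = p1[a] - p0[a];
    L2 += d[a] * d[a];
  }
  const double L = std::sqrt(L2);
  if (L <= 0.0) return 0.0;

  // clip [t0, t1] (parameter along p0->p1) to the volume bounding box
  double t0 = 0.0, t1 = 1.0;
  for (int a = 0; a < 3; ++a) {
    if (d[a] == 0.0) {
      if (p0[a] < lo[a] || p0[a] >= hi[a]) return 0.0;
    } else {
      double ta = (lo[a] - p0[a]) / d[a];
      double tb = (hi[a] - p0[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  if (t0 >= t1) return 0.0;

  // initial voxel index: nudge just inside the clipped span
  const double tin = t0 + 1e-12 * (t1 - t0);
  int idx[3], step[3];
  double tNext[3], tDelta[3];
  const double INF = std::numeric_limits<double>::infinity();
  for (int a = 0; a < 3; ++a) {
    double pa = p0[a] + tin * d[a];
    int i = (int)std::floor((pa - lo[a]) / sp[a]);
    if (i < 0) i = 0;
    if (i >= dim[a]) i = dim[a] - 1;
    idx[a] = i;
    if (d[a] > 0.0) {
      step[a] = 1;
      tDelta[a] = sp[a] / d[a];
      tNext[a] = (lo[a] + (i + 1) * sp[a] - p0[a]) / d[a];
    } else if (d[a] < 0.0) {
      step[a] = -1;
      tDelta[a] = -sp[a] / d[a];
      tNext[a] = (lo[a] + i * sp[a] - p0[a]) / d[a];
    } else {
      step[a] = 0;
      tDelta[a] = INF;
      tNext[a] = INF;
    }
  }

  const int nx = dim[0], nxy = dim[0] * dim[1];
  double acc = 0.0, tcur = t0;
  for (;;) {
    int amin = 0;
    if (tNext[1] < tNext[amin]) amin = 1;
    if (tNext[2] < tNext[amin]) amin = 2;
    double tstop = tNext[amin] < t1 ? tNext[amin] : t1;
    if (tstop > tcur) {
      double seg = (tstop - tcur) * L; // mm
      acc += dens[idx[0] + nx * idx[1] + nxy * idx[2]] * seg;
      tcur = tstop;
    }
    if (tNext[amin] >= t1) break;
    idx[amin] += step[amin];
    if (idx[amin] < 0 || idx[amin] >= dim[amin]) break;
    tNext[amin] += tDelta[amin];
  }
  return acc * 0.1; // g/cm^3 * mm -> g/cm^2
}

// [[Rcpp::export]]
double cpp_radiological_path(NumericVector density, IntegerVector dim,
                             NumericVector origin, NumericVector spacing,
                             NumericVector p0, NumericVector p1) {
  return traverse_areal(REAL(density), INTEGER(dim), REAL(origin),
                        REAL(spacing), REAL(p0), REAL(p1));
}

// Normalized depth-dose surrogate f(d) = (1 - exp(-beta d)) exp(-mu d) / f(d*),
// d in g/cm^2. Degenerate limits: mu = 0 -> pure buildup; beta = Inf -> pure
// attenuation with maximum at the surface.
static double dd_norm(double mu, double beta) {
  if (mu <= 0.0 || !R_FINITE(beta)) return 1.0;
  const double dstar = std::log((mu + beta) / mu) / beta;
  return (1.0 - std::exp(-beta * dstar)) * std::exp(-mu * dstar);
}

static double dd_factor(double d, double mu, double beta, double norm) {
  if (d < 0.0) d = 0.0;
  double f;
  if (!R_FINITE(beta)) {
    f = (mu > 0.0) ? std::exp(-mu * d) : 1.0;
  } else if (mu <= 0.0) {
    f = 1.0 - std::exp(-beta * d);
  } else {
    f = (1.0 - std::exp(-beta * d)) * std::exp(-mu * d);
  }
  return f / norm;
}

static inline double edge_profile(double q, double a, double b, double s) {
  const double r2 = std::sqrt(2.0) * s;
  return 0.5 * (std::erf((q - a) / r2) - std::erf((q - b) / r2));
}

// Dose of one divergent beam, evaluated at the voxel centers of an output
// grid (out_org/out_sp/out_dim) that may differ from the density grid; rays
// always traverse the full density volume. Geometry vectors are in world mm
// (z = depth, positive toward the detector bottom).
// [[Rcpp::export]]
NumericVector cpp_beam_dose(NumericVector density, IntegerVector dim,
                            NumericVector origin, NumericVector spacing,
                            NumericVector out_org, NumericVector out_sp,
                            IntegerVector out_dim,
                            NumericVector source, NumericVector bvec,
                            NumericVector uvec, NumericVector vvec,
                            NumericVector aperture, double sad,
                            double sigma_pen, double mu_eff, double beta,
                            double out_per_mu, double mu) {
  const int *dm = INTEGER(dim);
  const double *org = REAL(origin), *sp = REAL(spacing);
  const double *oo = REAL(out_org), *osp = REAL(out_sp);
  const double *S = REAL(source), *b = REAL(bvec), *u = REAL(uvec),
               *v = REAL(vvec);
  const double x1 = aperture[0], x2 = aperture[1], y1 = aperture[2],
               y2 = aperture[3];
  const int nx = out_dim[0], ny = out_dim[1], nk = out_dim[2];
  NumericVector out(Dimension(nx, ny, nk));
  double *o = REAL(out);
  const double norm = dd_norm(mu_eff, beta);
  const double scale = mu * out_per_mu;
  if (scale == 0.0) return out;

  double p[3], w[3];
  for (int kk = 0; kk < nk; ++kk) {
    p[2] = oo[2] + kk * osp[2];
    for (int j = 0; j < ny; ++j) {
      p[1] = oo[1] + j * osp[1];
      for (int i = 0; i < nx; ++i) {
        p[0] = oo[0] + i * osp[0];
        w[0] = p[0] - S[0];
        w[1] = p[1] - S[1];
        w[2] = p[2] - S[2];
        const double t = w[0] * b[0] + w[1] * b[1] + w[2] * b[2];
        if (t <= 1.0) { // behind or at the source
          o[i + nx * (j + (R_xlen_t)ny * kk)] = 0.0;
          continue;
        }
        const double r2 = w[0] * w[0] + w[1] * w[1] + w[2] * w[2];
        const double xb = (w[0] * u[0] + w[1] * u[1] + w[2] * u[2]) * sad / t;
        const double yb = (w[0] * v[0] + w[1] * v[1] + w[2] * v[2]) * sad / t;
        const double T =
            edge_profile(xb, x1, x2, sigma_pen) *
            edge_profile(yb, y1, y2, sigma_pen);
        double dose = 0.0;
        if (T > 1e-14) {
          const double areal =
              traverse_areal(REAL(density), dm, org, sp, S, p);
          dose = scale * T * dd_factor(areal, mu_eff, beta, norm) *
                 (sad * sad / r2);
        }
        o[i + nx * (j + (R_xlen_t)ny * kk)] = dose;
      }
    }
  }
  return out;
}
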