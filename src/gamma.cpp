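#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

struct Offset {
  double dx, dy, d2;
};

// 2D gamma index, global (Van Dyk) normalization. For every reference pixel
// inside the ROI, minimize
//   gamma^2 = ((D_e(r) - D_r)/dd_abs)^2 + (|r - r_ref|/dta)^2
// over displacements r within a disc of radius `radius`, exhaustively on a
// sub-pixel lattice of pitch `step` with the evaluated dose bilinearly
// interpolated. Offsets are visited in order of increasing distance so the
// search can stop once the distance term alone exceeds the current minimum.
// [[Rcpp::export]]
NumericMatrix cpp_gamma_map(NumericMatrix ref, NumericMatrix ev,
                            NumericVector ref_org, NumericVector ref_sp,
                            NumericVector ev_org, NumericVector ev_sp,
                            LogicalMatrix roi, double dd_abs, double dta,
                            double radius, double step) {
  const int nrx = ref.nrow(), nry = ref.ncol();
  const int nex = ev.nrow(), ney = ev.ncol();
  NumericMatrix g(nrx, nry);
  const double INF = std::numeric_limits<double>::infinity();
  const double dd2 = dd_abs * dd_abs, dta2 = dta * dta;

  std::vector<Offset> offs;
  const int m = (int)std::floor(radius / step);
  offs.reserve((2 * m + 1) * (2 * m + 1));
  for (int a = -m; a <= m; ++a)
    for (int b = -m; b <= m; ++b) {
      const double dx = a * step, dy = b * step, d2 = dx * dx + dy * dy;
      if (d2 <= radius * radius) offs.push_back({dx, dy, d2});
    }
  std::sort(offs.begin(), offs.end(),
            [](const Offset &a, const Offset &b) { return a.d2 < b.d2; });

  auto ev_at = [&](double x, double y, bool &ok) -> double {
    const double fi = (x - ev_org[0]) / ev_sp[0];
    const double fj = (y - ev_org[1]) / ev_sp[1];
    if (fi < 0.0 || fi > nex - 1 || fj < 0.0 || fj > ney - 1) {
      ok = false;
      return 0.0;
    }
    int i0 = (int)std::floor(fi), j0 = (int)std::floor(fj);
    if (i0 > nex - 2) i0 = nex - 2;
    if (j0 > ney - 2) j0 = ney - 2;
    const double wi = fi - i0, wj = fj - j0;
    const double v00 = ev(i0, j0), v10 = ev(i0 + 1, j0),
                 v01 = ev(i0, j0 + 1), v11 = ev(i0 + 1, j0 + 1);
    if (!R_FINITE(v00) || !R_FINITE(v10) || !R_FINITE(v01) ||
        !R_FINITE(v11)) {
      ok = false;
      return 0.0;
    }
    ok = true;
    return (1 - wi) * (1 - wj) * v00 + wi * (1 - wj) * v10 +
           (1 - wi) * wj * v01 + wi * wj * v11;
  };

  for (int j = 0; j < nry; ++j) {
    const double yr = ref_org[1] + j * ref_sp[1];
    for (int i = 0; i < nrx; ++i) {
      if (!roi(i, j) || !R_FINITE(ref(i, j))) {
        g(i, j) = NA_REAL;
        continue;
      }
      const double xr = ref_org[0] + i * ref_sp[0];
      const double Dr = ref(i, j);
      double best = INF;
      for (const Offset &o : offs) {
        const double dist2 = o.d2 / dta2;
        if (dist2 >= best) break;
        bool ok;
        const double De = ev_at(xr + o.dx, yr + o.dy, ok);
        if (!ok) continue;
        const double dD = De - Dr;
        const double g2 = dD * dD / dd2 + dist2;
        if (g2 < best) best = g2;
      }
      g(i, j) = R_FINITE(best) ? std::sqrt(best) : NA_REAL;
    }
  }
  return g;
}
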