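#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area over a deterministic
// golden-section spiral lattice. Coordinates and radii in nm; returns
// per-atom accessible area in nm^2.
//
// A test point on the expanded sphere (r_i + probe) counts as exposed when it
// lies outside every other expanded sphere. The lattice is identical for all
// atoms, so results are bit-reproducible for a given n_points.

// [[Rcpp::export]]
NumericVector sasa_kernel(NumericMatrix xyz, NumericVector radii,
                          double probe, int n_points) {
  const int n = xyz.nrow();
  if (radii.size() != n) stop("radii length must match atom count");
  if (n_points < 1) stop("n_points must be positive");

  // golden-section spiral on the unit sphere
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - (2.0 * k + 1.0) / n_points;
    double rho = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * k;
    px[k] = rho * std::cos(th);
    py[k] = rho * std::sin(th);
    pz[k] = z;
  }

  NumericVector area(n);
  std::vector<int> nb;
  std::vector<double> nbx, nby, nbz, nbr2;
  nb.reserve(128);

  for (int i = 0; i < n; ++i) {
    const double ri = radii[i] + probe;
    nb.clear(); nbx.clear(); nby.clear(); nbz.clear(); nbr2.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double rj = radii[j] + probe;
      const double dx = xyz(j, 0) - xyz(i, 0);
      const double dy = xyz(j, 1) - xyz(i, 1);
      const double dz = xyz(j, 2) - xyz(i, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double lim = ri + rj;
      if (d2 < lim * lim) {
        nb.push_back(j);
        nbx.push_back(xyz(j, 0)); nby.push_back(xyz(j, 1));
        nbz.push_back(xyz(j, 2)); nbr2.push_back(rj * rj);
      }
    }
    int exposed = 0;
    const size_t m = nb.size();
    for (int k = 0; k < n_points; ++k) {
      const double tx = xyz(i, 0) + ri * px[k];
      const double ty = xyz(i, 1) + ri * py[k];
      const double tz = xyz(i, 2) + ri * pz[k];
      bool occluded = false;
      for (size_t q = 0; q < m; ++q) {
        const double dx = tx - nbx[q];
        const double dy = ty - nby[q];
        const double dz = tz - nbz[q];
        if (dx * dx + dy * dy + dz * dz < nbr2[q]) { occluded = true; break; }
      }
      if (!occluded) ++exposed;
    }
    area[i] = 4.0 * M_PI * ri * ri * ((double) exposed / (double) n_points);
  }
  return area;
}
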