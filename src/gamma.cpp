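#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Offset {
  double r2;          // squared spatial distance, cm^2
  double fx, fy, fz;  // offset in fractional voxel-index units
};

// trilinear interpolation in voxel-center index coordinates;
// returns false when the point leaves the grid interior
inline bool interp(const double *v, int nx, int ny, int nz,
                   double fx, double fy, double fz, double &out) {
  if (fx < 0 || fy < 0 || fz < 0 ||
      fx > nx - 1 || fy > ny - 1 || fz > nz - 1) return false;
  int i = (int)std::floor(fx); if (i > nx - 2) i = nx - 2;
  int j = (int)std::floor(fy); if (j > ny - 2) j = ny - 2;
  int k = (int)std::floor(fz); if (k > nz - 2) k = nz - 2;
  const double ax = fx - i, ay = fy - j, az = fz - k;
  const R_xlen_t s = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
  const R_xlen_t dy = nx, dz = (R_xlen_t)nx * ny;
  const double c00 = v[s] * (1 - ax) + v[s + 1] * ax;
  const double c10 = v[s + dy] * (1 - ax) + v[s + dy + 1] * ax;
  const double c01 = v[s + dz] * (1 - ax) + v[s + dz + 1] * ax;
  const double c11 = v[s + dy + dz] * (1 - ax) + v[s + dy + dz + 1] * ax;
  out = (c00 * (1 - ay) + c10 * ay) * (1 - az) +
        (c01 * (1 - ay) + c11 * ay) * az;
  return true;
}

}  // namespace

// 3D gamma index of an evaluated dose against a reference dose on the
// same grid. For each reference voxel above `thresh`, the minimum over a
// refined spatial neighborhood of
//   sqrt(dr^2 / dta^2 + (D_eval - D_ref)^2 / dd^2)
// is found, with the evaluated dose trilinearly interpolated. Offsets are
// visited in order of increasing distance, so the search can stop as soon
// as the spatial term alone exceeds the best gamma found.
// [[Rcpp::export]]
List cpp_gamma3d(NumericVector eval, NumericVector ref, IntegerVector dims,
                 NumericVector spacing, double dd, double dta,
                 double thresh, int refine, double search_factor) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const double radius = search_factor * dta;
  const double stx = spacing[0] / refine;
  const double sty = spacing[1] / refine;
  const double stz = spacing[2] / refine;
  const int mx = (int)std::floor(radius / stx);
  const int my = (int)std::floor(radius / sty);
  const int mz = (int)std::floor(radius / stz);

  std::vector<Offset> offs;
  offs.reserve((2 * mx + 1) * (2 * my + 1) * (2 * mz + 1));
  for (int i = -mx; i <= mx; ++i)
    for (int j = -my; j <= my; ++j)
      for (int k = -mz; k <= mz; ++k) {
        const double ox = i * stx, oy = j * sty, oz = k * stz;
        const double r2 = ox * ox + oy * oy + oz * oz;
        if (r2 <= radius * radius) {
          offs.push_back({r2, ox / spacing[0], oy / spacing[1],
                          oz / spacing[2]});
        }
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset &a, const Offset &b) { return a.r2 < b.r2; });

  const double dd2 = dd * dd, dta2 = dta * dta;
  NumericVector gamma(nvox, NA_REAL);
  R_xlen_t n_eval = 0, n_pass = 0;
  const double *ev = REAL(eval), *rv = REAL(ref);

  for (int kz = 0; kz < nz; ++kz)
    for (int ky = 0; ky < ny; ++ky)
      for (int kx = 0; kx < nx; ++kx) {
        const R_xlen_t vi = kx + (R_xlen_t)nx * (ky + (R_xlen_t)ny * kz);
        const double dref = rv[vi];
        if (dref <= thresh) continue;
        double g2min = 1e300;
        for (size_t o = 0; o < offs.size(); ++o) {
          const double drterm = offs[o].r2 / dta2;
          if (drterm >= g2min) break;  // offsets sorted by distance
          double de;
          if (!interp(ev, nx, ny, nz, kx + offs[o].fx, ky + offs[o].fy,
                      kz + offs[o].fz, de)) continue;
          const double dd_ = de - dref;
          const double g2 = drterm + dd_ * dd_ / dd2;
          if (g2 < g2min) g2min = g2;
        }
        gamma[vi] = std::sqrt(g2min);
        ++n_eval;
        if (g2min <= 1.0) ++n_pass;
      }

  return List::create(_["gamma"] = gamma,
                      _["n_evaluated"] = (double)n_eval,
                      _["n_pass"] = (double)n_pass);
}
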