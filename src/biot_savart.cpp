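#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Magnetic vector potential of a finite straight current segment, in units of
// mu0*I/(4*pi). For a segment of length L and distances r1, r2 from the field
// point to the two endpoints, the closed form is
//   A = ln((r1 + r2 + L) / (r1 + r2 - L)) * u,
// with u the unit vector along the segment. Points closer to the segment axis
// than `excl` are clamped to distance `excl` (counted in `n_clamped`).
//
// `points` is an N x 3 matrix; the result is accumulated into `acc` (N x 3)
// scaled by `weight` (current sign/magnitude).
// [[Rcpp::export(name = ".segment_potential_accum")]]
int segment_potential_accum(NumericMatrix points,
                            NumericVector start, NumericVector end,
                            double weight, double excl,
                            NumericMatrix acc) {
  const int n = points.nrow();
  const double sx = start[0], sy = start[1], sz = start[2];
  double dx = end[0] - sx, dy = end[1] - sy, dz = end[2] - sz;
  const double L = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (L <= 0.0) stop("zero-length wire segment");
  const double ux = dx / L, uy = dy / L, uz = dz / L;
  int n_clamped = 0;
  for (int i = 0; i < n; ++i) {
    const double px = points(i, 0) - sx;
    const double py = points(i, 1) - sy;
    const double pz = points(i, 2) - sz;
    // axial coordinate t along segment and squared radial distance rho2
    const double t = px * ux + py * uy + pz * uz;
    double rho2 = px * px + py * py + pz * pz - t * t;
    if (rho2 < 0.0) rho2 = 0.0;
    double rho = std::sqrt(rho2);
    if (rho < excl && t > -excl && t < L + excl) {
      rho = excl;  // clamp on-axis singularity
      ++n_clamped;
    }
    const double r1 = std::sqrt(rho * rho + t * t);
    const double t2 = t - L;
    const double r2 = std::sqrt(rho * rho + t2 * t2);
    double denom = r1 + r2 - L;
    const double dmin = 1e-12 * (L > 1.0 ? L : 1.0);
    if (denom < dmin) denom = dmin;
    const double val = weight * std::log((r1 + r2 + L) / denom);
    acc(i, 0) += val * ux;
    acc(i, 1) += val * uy;
    acc(i, 2) += val * uz;
  }
  return n_clamped;
}
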