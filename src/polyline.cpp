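// Polyline utilities: exact-chord resampling (sphere marching) used when
// fiber trajectories are discretized at uniform spacing.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".resample_chord_cpp")]]
NumericMatrix resample_chord_cpp(NumericMatrix pts, double spacing) {
  const int n = pts.nrow();
  std::vector<double> ox, oy, oz;
  double cx = pts(0, 0), cy = pts(0, 1), cz = pts(0, 2);
  ox.push_back(cx); oy.push_back(cy); oz.push_back(cz);
  const double sp2 = spacing * spacing;
  int i = 0;
  while (i < n - 1) {
    // advance to the first vertex beyond `spacing` from the current point
    while (i < n - 1) {
      double dx = pts(i + 1, 0) - cx, dy = pts(i + 1, 1) - cy,
             dz = pts(i + 1, 2) - cz;
      if (dx * dx + dy * dy + dz * dz >= sp2) break;
      ++i;
    }
    if (i >= n - 1) break;
    // intersect segment [pts_i, pts_{i+1}] with the sphere (current, spacing)
    double ax = pts(i, 0), ay = pts(i, 1), az = pts(i, 2);
    double dx = pts(i + 1, 0) - ax, dy = pts(i + 1, 1) - ay,
           dz = pts(i + 1, 2) - az;
    double fx = ax - cx, fy = ay - cy, fz = az - cz;
    double A = dx * dx + dy * dy + dz * dz;
    double B = 2.0 * (fx * dx + fy * dy + fz * dz);
    double C = fx * fx + fy * fy + fz * fz - sp2;
    double disc = B * B - 4.0 * A * C;
    double t = 1.0;
    if (disc > 0 && A > 0) t = (-B + std::sqrt(disc)) / (2.0 * A);
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    cx = ax + t * dx; cy = ay + t * dy; cz = az + t * dz;
    ox.push_back(cx); oy.push_back(cy); oz.push_back(cz);
  }
  NumericMatrix out(ox.size(), 3);
  for (size_t k = 0; k < ox.size(); ++k) {
    out(k, 0) = ox[k]; out(k, 1) = oy[k]; out(k, 2) = oz[k];
  }
  return out;
}
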