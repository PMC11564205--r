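#include <Rcpp.h>
using namespace Rcpp;

// Constant-chord rediscretization of a polyline.
//
// Starting from the first vertex, each successive point is the first
// intersection, walking forward along the polyline, of the polyline with the
// circle of radius p centred on the previous rediscretized point. Vertices
// strictly inside the circle are skipped; the exit crossing on the containing
// segment is solved as the larger root of the quadratic
// |a + t(b - a) - c|^2 = p^2, t in [0, 1].
//
// Floating point can leave the walker marginally outside the circle when a
// chord ends within rounding error of a vertex; in that case the current
// position itself is taken as the crossing (its distance from the centre is
// p up to that same rounding error).
// [[Rcpp::export]]
NumericMatrix redisc_chord(NumericMatrix xy, double p) {
  const int n = xy.nrow();
  if (n < 2 || !(p > 0)) return NumericMatrix(0, 2);

  std::vector<double> rx, ry;
  double cx = xy(0, 0), cy = xy(0, 1);  // centre = last rediscretized point
  rx.push_back(cx); ry.push_back(cy);

  double ax = cx, ay = cy;              // current position on the polyline
  int i = 0;                            // segment index: from pos toward vertex i+1

  while (i + 1 < n) {
    const double bx = xy(i + 1, 0), by = xy(i + 1, 1);
    const double fx = ax - cx, fy = ay - cy;
    const double C = fx * fx + fy * fy - p * p;

    if (C >= 0) {                       // at/past the circle by rounding error
      cx = ax; cy = ay;
      rx.push_back(cx); ry.push_back(cy);
      continue;
    }

    const double dx = bx - ax, dy = by - ay;
    const double A = dx * dx + dy * dy;
    bool crossed = false;
    if (A > 0) {
      const double B = 2.0 * (fx * dx + fy * dy);
      const double disc = B * B - 4.0 * A * C;
      if (disc >= 0) {
        double t = (-B + std::sqrt(disc)) / (2.0 * A);  // exit root
        // a vertex lying on the circle (constant-step input) can land an
        // epsilon past t = 1 in floating point; accept crossings whose
        // overshoot moves the point by at most 1e-9 * p and clamp
        const double tolT = 1e-9 * p / std::sqrt(A);
        if (t > 1 && t <= 1 + tolT) t = 1;
        if (t >= 0 && t <= 1) {
          cx = ax + t * dx; cy = ay + t * dy;
          rx.push_back(cx); ry.push_back(cy);
          ax = cx; ay = cy;             // continue from the crossing, same segment
          crossed = true;
        }
      }
    }
    if (!crossed) { ax = bx; ay = by; ++i; }
  }

  NumericMatrix out(static_cast<int>(rx.size()), 2);
  for (size_t k = 0; k < rx.size(); ++k) {
    out(k, 0) = rx[k];
    out(k, 1) = ry[k];
  }
  return out;
}
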