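// Pixel rasterization of a worm body capsule: the set of integer pixels
// within width/2 of the central segment, optionally clipped to the image.
// Exact bounding-box scan; kept in C++ because the simulator renders one
// mask per worm per frame.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".renderCapsuleCpp")]]
IntegerMatrix renderCapsuleCpp(double cx, double cy, double theta,
                               double len, double width,
                               double imageW, double imageH, bool clip) {
  double r = width / 2.0;
  double hl = std::max((len - width) / 2.0, 0.0);
  double ux = std::cos(theta), uy = std::sin(theta);
  double ax = cx - hl * ux, ay = cy - hl * uy;
  double bx = cx + hl * ux, by = cy + hl * uy;
  int x0 = (int)std::floor(std::min(ax, bx) - r);
  int x1 = (int)std::ceil(std::max(ax, bx) + r);
  int y0 = (int)std::floor(std::min(ay, by) - r);
  int y1 = (int)std::ceil(std::max(ay, by) + r);
  double dx = bx - ax, dy = by - ay;
  double L2 = dx * dx + dy * dy, r2 = r * r;
  std::vector<int> xs, ys;
  xs.reserve(256); ys.reserve(256);
  for (int x = x0; x <= x1; ++x) {
    for (int y = y0; y <= y1; ++y) {
      double d2;
      if (L2 == 0.0) {
        double ex = x - ax, ey = y - ay;
        d2 = ex * ex + ey * ey;
      } else {
        double t = ((x - ax) * dx + (y - ay) * dy) / L2;
        if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
        double ex = x - (ax + t * dx), ey = y - (ay + t * dy);
        d2 = ex * ex + ey * ey;
      }
      if (d2 <= r2) {
        if (clip && (x < 0 || y < 0 || x >= imageW || y >= imageH)) continue;
        xs.push_back(x);
        ys.push_back(y);
      }
    }
  }
  int n = (int)xs.size();
  IntegerMatrix m(n, 2);
  for (int i = 0; i < n; ++i) { m(i, 0) = xs[i]; m(i, 1) = ys[i]; }
  colnames(m) = CharacterVector::create("x", "y");
  return m;
}
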