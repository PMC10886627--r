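#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Scanline rasterization of a union of polygons onto the pixel-center grid.
//
// Pixel (row r, col c), 0-based, has center (c + 0.5, r + 0.5); x grows
// rightward, y downward (image convention).  A pixel is covered by one
// polygon when its center lies inside under the even-odd rule over all of
// that polygon's rings (outer ring plus holes), and covered by the union
// when any polygon covers it.
//
// Even-odd semantics match the classical crossing test with strict
// comparison px < x_intersect and half-open edge span (y1 > py) != (y2 > py),
// so a per-pixel point-in-polygon loop reproduces this mask exactly.
//
// polygons: list of polygons; each polygon is a list of rings; each ring an
// n x 2 matrix of (x, y) vertices (closing vertex optional).
// [[Rcpp::export(name = ".rasterize_polygons")]]
LogicalMatrix rasterize_polygons(List polygons, int height, int width) {
  LogicalMatrix mask(height, width);
  std::vector<double> xs;
  for (int p = 0; p < polygons.size(); ++p) {
    List rings(polygons[p]);
    for (int r = 0; r < height; ++r) {
      double py = r + 0.5;
      xs.clear();
      for (int k = 0; k < rings.size(); ++k) {
        NumericMatrix ring(rings[k]);
        int n = ring.nrow();
        if (n < 3) continue;
        for (int i = 0; i < n; ++i) {
          int j = (i + 1) % n;
          double x1 = ring(i, 0), y1 = ring(i, 1);
          double x2 = ring(j, 0), y2 = ring(j, 1);
          if ((y1 > py) != (y2 > py)) {
            xs.push_back(x1 + (py - y1) * (x2 - x1) / (y2 - y1));
          }
        }
      }
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      // fill half-open spans [xs[2i], xs[2i+1]): centers with
      // xs[2i] <= px < xs[2i+1] have an odd strict-right crossing count
      for (size_t i = 0; i + 1 < xs.size(); i += 2) {
        int c0 = (int)std::ceil(xs[i] - 0.5);
        int c1 = (int)std::ceil(xs[i + 1] - 0.5) - 1;
        if (c0 < 0) c0 = 0;
        if (c1 > width - 1) c1 = width - 1;
        for (int c = c0; c <= c1; ++c) mask(r, c) = true;
      }
    }
  }
  return mask;
}

// Per-tile covered-pixel counts for a non-overlapping grid of square tiles.
// origins: m x 2 integer matrix of 0-based (x, y) tile corners.
// [[Rcpp::export(name = ".tile_cover_counts")]]
IntegerVector tile_cover_counts(LogicalMatrix mask, IntegerMatrix origins,
                                int tile_size) {
  int m = origins.nrow();
  IntegerVector out(m);
  for (int t = 0; t < m; ++t) {
    int x0 = origins(t, 0), y0 = origins(t, 1);
    int cnt = 0;
    for (int r = y0; r < y0 + tile_size; ++r)
      for (int c = x0; c < x0 + tile_size; ++c)
        if (mask(r, c)) ++cnt;
    out[t] = cnt;
  }
  return out;
}
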