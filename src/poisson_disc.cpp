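#include <Rcpp.h>
using namespace Rcpp;

// Greedy dart throwing for a variable-density Poisson-disc pattern on a
// discrete grid. Candidates are visited in the order given (the caller
// shuffles with R's RNG so seeding stays on the R side). Candidate i is
// accepted iff its distance to every previously accepted point j satisfies
// d(i, j) >= min(radii[i], radii[j]). A uniform background grid with cell
// size `cell` (<= the smallest radius) and a linked list per cell keeps the
// neighbourhood search local.
// [[Rcpp::export]]
LogicalVector pd_darts(NumericMatrix pts, NumericVector radii,
                       double cell, double rmax) {
  const int n = pts.nrow();
  LogicalVector accept(n);
  if (n == 0) return accept;

  double minx = pts(0, 0), maxx = pts(0, 0);
  double miny = pts(0, 1), maxy = pts(0, 1);
  for (int i = 1; i < n; ++i) {
    minx = std::min(minx, pts(i, 0)); maxx = std::max(maxx, pts(i, 0));
    miny = std::min(miny, pts(i, 1)); maxy = std::max(maxy, pts(i, 1));
  }
  const int ncx = (int)std::floor((maxx - minx) / cell) + 1;
  const int ncy = (int)std::floor((maxy - miny) / cell) + 1;
  std::vector<int> head((size_t)ncx * ncy, -1);
  std::vector<int> nxt(n, -1);
  const int w = (int)std::ceil(rmax / cell);

  for (int i = 0; i < n; ++i) {
    const double x = pts(i, 0), y = pts(i, 1), ri = radii[i];
    const int cx = (int)std::floor((x - minx) / cell);
    const int cy = (int)std::floor((y - miny) / cell);
    bool ok = true;
    for (int ax = std::max(0, cx - w); ok && ax <= std::min(ncx - 1, cx + w); ++ax) {
      for (int ay = std::max(0, cy - w); ok && ay <= std::min(ncy - 1, cy + w); ++ay) {
        for (int j = head[(size_t)ax * ncy + ay]; j != -1; j = nxt[j]) {
          const double dx = x - pts(j, 0), dy = y - pts(j, 1);
          const double r = std::min(ri, radii[j]);
          if (dx * dx + dy * dy < r * r) { ok = false; break; }
        }
      }
    }
    if (ok) {
      accept[i] = true;
      const size_t c = (size_t)cx * ncy + cy;
      nxt[i] = head[c];
      head[c] = i;
    }
  }
  return accept;
}
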