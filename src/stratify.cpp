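#include <Rcpp.h>
#include <vector>
#include <utility>
#include <cmath>
using namespace Rcpp;

// Half-sample symmetric reflection of a 0-based bin index into [0, n).
static inline int fold_index(int j, int n) {
  while (j < 0 || j >= n) {
    if (j < 0) j = -1 - j;
    else j = 2 * n - 1 - j;
  }
  return j;
}

// Per-cell stratification thresholds.
//
// For every occupied grid cell: pool the height histogram of all points in
// cells whose centre lies within radius_cells of the cell (the "locale"),
// smooth it with the supplied kernel (reflection at the boundaries), take
// the maximal runs of negative second difference as canopy layers, and set
// the threshold to the midpoint between the lower edge of the top run and
// the upper edge of the run below it. One run -> threshold 0 (everything
// left is one layer); no runs or a locale with fewer than min_pts points ->
// NA (caller inherits from the nearest resolved cell).
//
// [[Rcpp::export]]
NumericMatrix cell_thresholds_cpp(IntegerVector ix, IntegerVector iy,
                                  IntegerVector hbin, int nx, int ny,
                                  int nbins, double bin_width,
                                  double radius_cells, NumericVector kernel,
                                  int min_pts) {
  std::vector<int> counts(static_cast<size_t>(nx) * ny * nbins, 0);
  std::vector<int> cellcount(static_cast<size_t>(nx) * ny, 0);
  const int npts = ix.size();
  for (int p = 0; p < npts; ++p) {
    const size_t c = static_cast<size_t>(ix[p]) * ny + iy[p];
    counts[c * nbins + hbin[p]]++;
    cellcount[c]++;
  }
  const int rint = static_cast<int>(std::floor(radius_cells));
  std::vector<std::pair<int, int> > disk;
  for (int dx = -rint; dx <= rint; ++dx)
    for (int dy = -rint; dy <= rint; ++dy)
      if (static_cast<double>(dx) * dx + static_cast<double>(dy) * dy <=
          radius_cells * radius_cells)
        disk.push_back(std::make_pair(dx, dy));
  const int klen = kernel.size(), khalf = klen / 2;
  NumericMatrix thr(nx, ny);
  std::fill(thr.begin(), thr.end(), NA_REAL);
  std::vector<double> hist(nbins), sm(nbins), d2(nbins);
  for (int cx = 0; cx < nx; ++cx) {
    for (int cy = 0; cy < ny; ++cy) {
      if (cellcount[static_cast<size_t>(cx) * ny + cy] == 0) continue;
      std::fill(hist.begin(), hist.end(), 0.0);
      long total = 0;
      for (size_t o = 0; o < disk.size(); ++o) {
        const int qx = cx + disk[o].first, qy = cy + disk[o].second;
        if (qx < 0 || qx >= nx || qy < 0 || qy >= ny) continue;
        const size_t q = static_cast<size_t>(qx) * ny + qy;
        if (cellcount[q] == 0) continue;
        const int *col = &counts[q * nbins];
        for (int b = 0; b < nbins; ++b) hist[b] += col[b];
        total += cellcount[q];
      }
      if (total < min_pts) continue;  // degenerate locale
      if (nbins < 3) continue;
      for (int b = 0; b < nbins; ++b) {
        double acc = 0.0;
        for (int k = 0; k < klen; ++k)
          acc += kernel[k] * hist[fold_index(b + k - khalf, nbins)];
        sm[b] = acc;
      }
      for (int b = 1; b < nbins - 1; ++b)
        d2[b] = sm[b - 1] - 2.0 * sm[b] + sm[b + 1];
      d2[0] = sm[0] - 2.0 * sm[1] + sm[2];
      d2[nbins - 1] = sm[nbins - 3] - 2.0 * sm[nbins - 2] + sm[nbins - 1];
      // top-down scan for the two topmost negative-curvature runs
      int b = nbins - 1;
      while (b >= 0 && !(d2[b] < 0)) --b;
      if (b < 0) continue;            // no salient range: NA
      while (b >= 0 && d2[b] < 0) --b;
      const int lo1 = b + 1;          // lower bin of top run
      while (b >= 0 && !(d2[b] < 0)) --b;
      if (b < 0) {                    // single run: whole column is one layer
        thr(cx, cy) = 0.0;
        continue;
      }
      const int hi2 = b;              // upper bin of second run
      thr(cx, cy) = 0.5 * (lo1 * bin_width + (hi2 + 1) * bin_width);
    }
  }
  return thr;
}

// For each query cell, index (1-based) of the nearest reference cell.
// [[Rcpp::export]]
IntegerVector nearest_cell_cpp(IntegerVector qx, IntegerVector qy,
                               IntegerVector rx, IntegerVector ry) {
  const int nq = qx.size(), nr = rx.size();
  IntegerVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    int arg = 1;
    for (int j = 0; j < nr; ++j) {
      const double dx = qx[i] - rx[j], dy = qy[i] - ry[j];
      const double d = dx * dx + dy * dy;
      if (d < best) { best = d; arg = j + 1; }
    }
    out[i] = arg;
  }
  return out;
}
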