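#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// All-nearest-neighbor search over a 2-D point set using a uniform grid
// hash. For each point, returns the 1-based index of the nearest *other*
// point by Euclidean distance. Exact ties are broken toward the candidate
// with the smaller (row, col), then the smaller index. Expected O(n) for
// roughly uniform point sets; used by the same-color neighbor statistic,
// where n can reach ~7e4 per Monte Carlo replicate.
// [[Rcpp::export]]
IntegerVector nn_nearest_index(NumericVector row, NumericVector col) {
  const int n = row.size();
  if (col.size() != n) stop("row and col must have equal length");
  if (n < 2) stop("need at least two points");

  double rmin = row[0], rmax = row[0], cmin = col[0], cmax = col[0];
  for (int i = 1; i < n; ++i) {
    rmin = std::min(rmin, row[i]); rmax = std::max(rmax, row[i]);
    cmin = std::min(cmin, col[i]); cmax = std::max(cmax, col[i]);
  }
  double extent = std::max(rmax - rmin, cmax - cmin);
  if (extent <= 0) extent = 1.0;  // all points coincide

  // Aim for ~1 point per cell.
  int ncell = std::max(1, (int)std::floor(std::sqrt((double)n)));
  double cs = extent / ncell;
  int nr = (int)std::floor((rmax - rmin) / cs) + 1;
  int nc = (int)std::floor((cmax - cmin) / cs) + 1;

  std::vector<int> cell(n);
  std::vector<int> count((size_t)nr * nc + 1, 0);
  for (int i = 0; i < n; ++i) {
    int cr = std::min(nr - 1, (int)std::floor((row[i] - rmin) / cs));
    int cc = std::min(nc - 1, (int)std::floor((col[i] - cmin) / cs));
    cell[i] = cr * nc + cc;
    ++count[cell[i] + 1];
  }
  for (size_t k = 1; k < count.size(); ++k) count[k] += count[k - 1];
  std::vector<int> order(n);
  {
    std::vector<int> pos(count.begin(), count.end() - 1);
    for (int i = 0; i < n; ++i) order[pos[cell[i]]++] = i;
  }

  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const double ri = row[i], ci = col[i];
    const int cri = cell[i] / nc, cci = cell[i] % nc;
    double best_d2 = R_PosInf;
    int best = -1;
    const int kmax = std::max(nr, nc);
    for (int k = 0; k <= kmax; ++k) {
      // Any point in a cell at Chebyshev ring k is at distance >= (k-1)*cs.
      if (best >= 0) {
        double lower = (k - 1) * cs;
        if (lower > 0 && lower * lower > best_d2) break;
      }
      int rlo = cri - k, rhi = cri + k, clo = cci - k, chi = cci + k;
      for (int cr = rlo; cr <= rhi; ++cr) {
        if (cr < 0 || cr >= nr) continue;
        bool edge_row = (cr == rlo || cr == rhi);
        for (int cc = clo; cc <= chi; ++cc) {
          if (cc < 0 || cc >= nc) continue;
          if (!edge_row && cc != clo && cc != chi) continue;  // ring only
          int c = cr * nc + cc;
          for (int p = count[c]; p < count[c + 1]; ++p) {
            int j = order[p];
            if (j == i) continue;
            double dr = row[j] - ri, dc = col[j] - ci;
            double d2 = dr * dr + dc * dc;
            if (d2 < best_d2) {
              best_d2 = d2; best = j;
            } else if (d2 == best_d2 && best >= 0) {
              if (row[j] < row[best] ||
                  (row[j] == row[best] && col[j] < col[best]) ||
                  (row[j] == row[best] && col[j] == col[best] && j < best)) {
                best = j;
              }
            }
          }
        }
      }
    }
    out[i] = best + 1;
  }
  return out;
}
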