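#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Marker-controlled watershed by ascending-intensity flooding.
//
// Semantics (deterministic, matched by the brute-force reference used in
// the test suite): repeatedly take, among all unlabeled masked pixels that
// are 8-adjacent to a labeled pixel, the one with the smallest
// (intensity, row-major index) and assign it the label of the neighbor the
// flood arrives through: the labeled 8-neighbor with the smallest
// (intensity, label id). Exact intensity ties therefore resolve to the
// lower (earlier, row-major) seed id. Implemented with a priority queue
// keyed by the static (value, index) pair; stale entries skipped at pop.
//
// values: intensity matrix (the smoothed image)
// seeds:  integer matrix, 0 = unlabeled, k > 0 = seed label k
// mask:   logical matrix; pixels outside the mask are never labeled
// [[Rcpp::export(name = ".ws_flood")]]
IntegerMatrix ws_flood(NumericMatrix values, IntegerMatrix seeds,
                       LogicalMatrix mask) {
  const int nr = values.nrow(), nc = values.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc ||
      mask.nrow() != nr || mask.ncol() != nc)
    stop("values, seeds and mask must have identical dimensions");

  IntegerMatrix lab(nr, nc);
  typedef std::pair<double, int> Entry;  // (value, row-major index)
  std::priority_queue<Entry, std::vector<Entry>, std::greater<Entry> > pq;

  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  // row-major index so that ties break in row-major (reading) order
  #define RM(i, j) ((i) * nc + (j))

  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      lab(i, j) = (mask(i, j) && seeds(i, j) > 0) ? seeds(i, j) : 0;

  // enqueue unlabeled masked neighbors of all seeds
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      if (lab(i, j) <= 0) continue;
      for (int n = 0; n < 8; ++n) {
        int ii = i + di[n], jj = j + dj[n];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (mask(ii, jj) && lab(ii, jj) == 0)
          pq.push(Entry(values(ii, jj), RM(ii, jj)));
      }
    }

  while (!pq.empty()) {
    Entry e = pq.top();
    pq.pop();
    int idx = e.second, i = idx / nc, j = idx % nc;
    if (lab(i, j) != 0) continue;  // stale entry
    int best = 0;
    double bestv = 0;
    for (int n = 0; n < 8; ++n) {
      int ii = i + di[n], jj = j + dj[n];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      int l = lab(ii, jj);
      if (l <= 0) continue;
      double vn = values(ii, jj);
      if (best == 0 || vn < bestv || (vn == bestv && l < best)) {
        best = l;
        bestv = vn;
      }
    }
    if (best == 0) continue;  // should not happen
    lab(i, j) = best;
    for (int n = 0; n < 8; ++n) {
      int ii = i + di[n], jj = j + dj[n];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (mask(ii, jj) && lab(ii, jj) == 0)
        pq.push(Entry(values(ii, jj), RM(ii, jj)));
    }
  }
  #undef RM
  return lab;
}
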