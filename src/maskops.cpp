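#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Pixels 4-connected-reachable from the image border through non-blocked
// pixels. Used to fill outlines: everything NOT reached is outline+interior.
// [[Rcpp::export]]
LogicalMatrix cpp_flood_outside(LogicalMatrix blocked) {
  int nr = blocked.nrow(), nc = blocked.ncol();
  LogicalMatrix reached(nr, nc);
  std::queue<int> q;
  auto push = [&](int i, int j) {
    if (!blocked(i, j) && !reached(i, j)) { reached(i, j) = true; q.push(i + j * nr); }
  };
  for (int i = 0; i < nr; ++i) { push(i, 0); push(i, nc - 1); }
  for (int j = 0; j < nc; ++j) { push(0, j); push(nr - 1, j); }
  const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
  while (!q.empty()) {
    int p = q.front(); q.pop();
    int i = p % nr, j = p / nr;
    for (int d = 0; d < 4; ++d) {
      int ii = i + di[d], jj = j + dj[d];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      push(ii, jj);
    }
  }
  return reached;
}

// Connected-component labelling by BFS; connectivity 4 or 8; labels assigned
// in column-major scan order, background 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int di8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dj8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  int nnb = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::queue<int> q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(i + j * nr);
      while (!q.empty()) {
        int p = q.front(); q.pop();
        int pi = p % nr, pj = p / nr;
        for (int d = 0; d < nnb; ++d) {
          int ii = pi + di8[d], jj = pj + dj8[d];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) { lab(ii, jj) = next; q.push(ii + jj * nr); }
        }
      }
    }
  return lab;
}
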