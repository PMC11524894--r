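#include <Rcpp.h>
using namespace Rcpp;

// Two-pass union-find connected-component labeling of a binary raster.
// connectivity: 4 or 8. Returns 0 for background, labels 1..k in
// first-encounter (row-major over columns, R column-major storage) order.

static int find_root(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void unite(std::vector<int> &parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export]]
IntegerMatrix cc_label(const LogicalMatrix &mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);  // parent[0] unused
  int next = 1;

  // first pass: scan columns then rows (column-major), look "up" and "left"
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      int neigh[4];
      int nn = 0;
      if (r > 0 && mask(r - 1, c)) neigh[nn++] = lab(r - 1, c);
      if (c > 0 && mask(r, c - 1)) neigh[nn++] = lab(r, c - 1);
      if (connectivity == 8) {
        if (r > 0 && c > 0 && mask(r - 1, c - 1)) neigh[nn++] = lab(r - 1, c - 1);
        if (r < nr - 1 && c > 0 && mask(r + 1, c - 1)) neigh[nn++] = lab(r + 1, c - 1);
      }
      for (int k = 0; k < nn; ++k)
        if (best == 0 || neigh[k] < best) best = neigh[k];
      if (best == 0) {
        parent.push_back(next);
        lab(r, c) = next++;
      } else {
        lab(r, c) = best;
        for (int k = 0; k < nn; ++k) unite(parent, best, neigh[k]);
      }
    }
  }

  // second pass: resolve and compact labels
  std::vector<int> remap(next, 0);
  int out = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (lab(r, c) == 0) continue;
      int root = find_root(parent, lab(r, c));
      if (remap[root] == 0) remap[root] = ++out;
      lab(r, c) = remap[root];
    }
  }
  return lab;
}
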