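#include <Rcpp.h>
#include <vector>

// 8-connected two-pass connected-component labeling of a binary matrix.
// Returns an integer matrix of labels (0 = background, 1..n_components).

static int find_root(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];  // path halving
    i = parent[i];
  }
  return i;
}

static void unite(std::vector<int> &parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export(name = ".label8_cpp")]]
Rcpp::IntegerMatrix label8_cpp(const Rcpp::LogicalMatrix &mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  Rcpp::IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0);  // label 0 reserved for background
  int next = 1;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      // previously visited 8-neighbours: (r-1,c), (r-1,c-1), (r,c-1), (r+1,c-1)
      int neigh[4] = {0, 0, 0, 0};
      int nn = 0;
      if (r > 0 && lab(r - 1, c)) neigh[nn++] = lab(r - 1, c);
      if (c > 0) {
        if (r > 0 && lab(r - 1, c - 1)) neigh[nn++] = lab(r - 1, c - 1);
        if (lab(r, c - 1)) neigh[nn++] = lab(r, c - 1);
        if (r + 1 < nr && lab(r + 1, c - 1)) neigh[nn++] = lab(r + 1, c - 1);
      }
      if (nn == 0) {
        parent.push_back(next);
        lab(r, c) = next++;
      } else {
        int m = neigh[0];
        for (int k = 1; k < nn; ++k) m = std::min(m, neigh[k]);
        lab(r, c) = m;
        for (int k = 0; k < nn; ++k) unite(parent, m, neigh[k]);
      }
    }
  }

  // second pass: flatten labels to consecutive integers
  std::vector<int> remap(parent.size(), 0);
  int n_comp = 0;
  for (size_t i = 1; i < parent.size(); ++i) {
    int root = find_root(parent, (int)i);
    if (remap[root] == 0) remap[root] = ++n_comp;
    remap[i] = remap[root];
  }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c)) lab(r, c) = remap[lab(r, c)];
  return lab;
}
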