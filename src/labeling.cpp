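#include <Rcpp.h>
using namespace Rcpp;

static int find_root(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];  // path halving
    x = parent[x];
  }
  return x;
}

static void unite(std::vector<int>& parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra == rb) return;
  if (ra < rb) parent[rb] = ra; else parent[ra] = rb;
}

//' Connected-component labeling of a binary mask.
//'
//' Two-pass union-find labeling. With \code{eight = true} diagonal
//' neighbours are connected (8-connectivity), otherwise only edge
//' neighbours (4-connectivity). Components are numbered 1..k in order of
//' first appearance in a column-major scan; background stays 0.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, bool eight = true) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(256);
  parent.push_back(0);
  int next = 1;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int nb[4];
      int nnb = 0;
      if (i > 0 && mask(i - 1, j)) nb[nnb++] = lab(i - 1, j);
      if (j > 0 && mask(i, j - 1)) nb[nnb++] = lab(i, j - 1);
      if (eight && j > 0) {
        if (i > 0 && mask(i - 1, j - 1)) nb[nnb++] = lab(i - 1, j - 1);
        if (i + 1 < nr && mask(i + 1, j - 1)) nb[nnb++] = lab(i + 1, j - 1);
      }
      if (nnb == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        int m = nb[0];
        for (int k = 1; k < nnb; ++k) if (nb[k] < m) m = nb[k];
        lab(i, j) = m;
        for (int k = 0; k < nnb; ++k) unite(parent, m, nb[k]);
      }
    }
  }

  // second pass: compact root labels in order of first appearance
  std::vector<int> newlab(parent.size(), 0);
  int k = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (!l) continue;
      int r = find_root(parent, l);
      if (!newlab[r]) newlab[r] = ++k;
      lab(i, j) = newlab[r];
    }
  }
  return lab;
}
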