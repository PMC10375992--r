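#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass union-find connected-component labelling of a binary matrix.
// connectivity: 4 or 8. Labels are compacted to 1..n, background 0.

static int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);  // parent[0] unused
  int next = 1;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      int nbr[4];
      int nn = 0;
      if (r > 0 && mask(r - 1, c)) nbr[nn++] = lab(r - 1, c);
      if (c > 0 && mask(r, c - 1)) nbr[nn++] = lab(r, c - 1);
      if (connectivity == 8) {
        if (r > 0 && c > 0 && mask(r - 1, c - 1)) nbr[nn++] = lab(r - 1, c - 1);
        if (r < nr - 1 && c > 0 && mask(r + 1, c - 1)) nbr[nn++] = lab(r + 1, c - 1);
      }
      for (int k = 0; k < nn; ++k)
        if (best == 0 || nbr[k] < best) best = nbr[k];
      if (best == 0) {
        parent.push_back(next);
        lab(r, c) = next++;
      } else {
        lab(r, c) = best;
        for (int k = 0; k < nn; ++k) {
          int ra = find_root(parent, best), rb = find_root(parent, nbr[k]);
          if (ra != rb) parent[rb > ra ? rb : ra] = (rb > ra ? ra : rb);
        }
      }
    }
  }
  // compact labels
  std::vector<int> remap(next, 0);
  int n = 0;
  for (int i = 1; i < next; ++i) {
    int r = find_root(parent, i);
    if (remap[r] == 0) remap[r] = ++n;
  }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) lab(r, c) = remap[find_root(parent, lab(r, c))];
  return lab;
}
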