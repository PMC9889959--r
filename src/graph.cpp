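#include <Rcpp.h>
#include "vrna_common.h"

using namespace Rcpp;

// Pairwise base-pair distances (symmetric-difference cardinality) between
// dot-bracket structures of equal length.
// [[Rcpp::export]]
IntegerMatrix cpp_bp_dist_matrix(CharacterVector dbs) {
  int m = (int) dbs.size();
  std::vector<std::vector<short> > pts(m);
  for (int a = 0; a < m; ++a)
    pts[a] = ctf_pair_table(std::string(CHAR(STRING_ELT(dbs, a))));
  IntegerMatrix d(m, m);
  for (int a = 0; a < m; ++a) {
    for (int b = a + 1; b < m; ++b) {
      const std::vector<short> &x = pts[a], &y = pts[b];
      int n = x[0], dd = 0;
      for (int i = 1; i <= n; ++i) {
        if (x[i] != y[i]) {
          if (x[i] > i) ++dd;
          if (y[i] > i) ++dd;
        }
      }
      d(a, b) = dd;
      d(b, a) = dd;
    }
  }
  return d;
}

// Guide edges: (a,b) is a guide edge unless some node c satisfies
// max(d(a,c), d(c,b)) < d(a,b). Shortcut edges: for every node i and every
// pair (x,y) of guide neighbors of i, a shortcut is added when
// d(x,i) + d(i,y) > d(x,y) and (x,y) is not already a guide edge.
// [[Rcpp::export]]
List cpp_guide_edges(IntegerMatrix d) {
  int m = d.nrow();
  LogicalMatrix guide(m, m), shortcut(m, m);
  for (int a = 0; a < m; ++a) {
    for (int b = a + 1; b < m; ++b) {
      int dab = d(a, b);
      bool edge = true;
      for (int c = 0; c < m && edge; ++c) {
        if (c == a || c == b) continue;
        int mx = d(a, c) > d(c, b) ? d(a, c) : d(c, b);
        if (mx < dab) edge = false;
      }
      guide(a, b) = guide(b, a) = edge;
    }
  }
  for (int i = 0; i < m; ++i) {
    std::vector<int> nb;
    for (int a = 0; a < m; ++a)
      if (a != i && guide(i, a)) nb.push_back(a);
    for (size_t p = 0; p < nb.size(); ++p) {
      for (size_t q = p + 1; q < nb.size(); ++q) {
        int x = nb[p], y = nb[q];
        if (guide(x, y)) continue;
        if (d(x, i) + d(i, y) > d(x, y))
          shortcut(x, y) = shortcut(y, x) = true;
      }
    }
  }
  return List::create(_["guide"] = guide, _["shortcut"] = shortcut);
}
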