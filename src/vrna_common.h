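#ifndef COTRANSFOLD_VRNA_COMMON_H
#define COTRANSFOLD_VRNA_COMMON_H

#include <string>
#include <vector>
#include <cstring>
#include <cstdlib>

extern "C" {
#include <ViennaRNA/model.h>
#include <ViennaRNA/fold_compound.h>
#include <ViennaRNA/mfe.h>
#include <ViennaRNA/eval.h>
#include <ViennaRNA/constraints/basic.h>
#include <ViennaRNA/constraints/hard.h>
#include <ViennaRNA/utils/basic.h>
#include <ViennaRNA/utils/structures.h>
}

inline vrna_md_t ctf_model_details(double temperature, bool noLP) {
  vrna_md_t md;
  vrna_md_set_default(&md);
  md.temperature = temperature;
  md.noLP = noLP ? 1 : 0;
  return md;
}

/* 1-based pair table from a dot-bracket string; pt[0] holds the length */
inline std::vector<short> ctf_pair_table(const std::string &db) {
  int n = (int) db.size();
  std::vector<short> pt(n + 1, 0);
  pt[0] = (short) n;
  std::vector<int> stack;
  for (int i = 1; i <= n; ++i) {
    char c = db[i - 1];
    if (c == '(') {
      stack.push_back(i);
    } else if (c == ')') {
      int j = stack.back();
      stack.pop_back();
      pt[j] = (short) i;
      pt[i] = (short) j;
    }
  }
  return pt;
}

inline std::string ctf_db_from_pt(const std::vector<short> &pt) {
  int n = pt[0];
  std::string db(n, '.');
  for (int i = 1; i <= n; ++i) {
    if (pt[i] > i) { db[i - 1] = '('; db[pt[i] - 1] = ')'; }
  }
  return db;
}

inline bool ctf_canonical_pair(char a, char b) {
  switch (a) {
    case 'A': return b == 'U';
    case 'U': return b == 'A' || b == 'G';
    case 'G': return b == 'C' || b == 'U';
    case 'C': return b == 'G';
    default:  return false;
  }
}

#endif
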