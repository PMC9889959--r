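#include <Rcpp.h>
#include "vrna_common.h"

using namespace Rcpp;

// Free energy (kcal/mol) of each structure on `seq`, evaluated at the full
// length of `seq`. Structures must be dot-bracket strings of the same length.
// [[Rcpp::export]]
NumericVector cpp_eval_structures(std::string seq,
                                  CharacterVector structures,
                                  double temperature,
                                  bool noLP) {
  vrna_md_t md = ctf_model_details(temperature, noLP);
  vrna_fold_compound_t *fc =
      vrna_fold_compound(seq.c_str(), &md, VRNA_OPTION_EVAL_ONLY);
  NumericVector out(structures.size());
  for (R_xlen_t i = 0; i < structures.size(); ++i) {
    const char *db = CHAR(STRING_ELT(structures, i));
    if ((int) std::strlen(db) != (int) seq.size()) {
      vrna_fold_compound_free(fc);
      stop("structure length does not match sequence length");
    }
    out[i] = vrna_eval_structure(fc, db);
  }
  vrna_fold_compound_free(fc);
  return out;
}

// Constrained MFE fold. `constraint` uses the dot-bracket constraint dialect
// ('.', 'x', '(', ')', '<', '>'); an empty string means unconstrained.
// With enforce = TRUE, bracketed pairs are forced to form; otherwise they
// only exclude incompatible pairs.
// [[Rcpp::export]]
List cpp_mfe(std::string seq,
             std::string constraint,
             bool enforce,
             double temperature,
             bool noLP) {
  vrna_md_t md = ctf_model_details(temperature, noLP);
  vrna_fold_compound_t *fc =
      vrna_fold_compound(seq.c_str(), &md, VRNA_OPTION_MFE);
  if (!constraint.empty()) {
    if (constraint.size() != seq.size()) {
      vrna_fold_compound_free(fc);
      stop("constraint length does not match sequence length");
    }
    unsigned int opts = VRNA_CONSTRAINT_DB | VRNA_CONSTRAINT_DB_DOT |
                        VRNA_CONSTRAINT_DB_X | VRNA_CONSTRAINT_DB_RND_BRACK |
                        VRNA_CONSTRAINT_DB_ANG_BRACK;
    if (enforce) opts |= VRNA_CONSTRAINT_DB_ENFORCE_BP;
    vrna_constraints_add(fc, constraint.c_str(), opts);
  }
  std::vector<char> ss(seq.size() + 1, 0);
  float e = vrna_mfe(fc, ss.data());
  vrna_fold_compound_free(fc);
  bool feasible = R_finite(e) && e < 1e4;
  return List::create(_["structure"] = std::string(ss.data()),
                      _["energy"] = (double) e,
                      _["feasible"] = feasible);
}

// MFE over all structures whose base pairs are a subset of `pairs`
// (2-column 1-based matrix). All other base pairs are forbidden.
// [[Rcpp::export]]
List cpp_mfe_union(std::string seq,
                   IntegerMatrix pairs,
                   double temperature,
                   bool noLP) {
  int n = (int) seq.size();
  vrna_md_t md = ctf_model_details(temperature, noLP);
  vrna_fold_compound_t *fc =
      vrna_fold_compound(seq.c_str(), &md, VRNA_OPTION_MFE);
  vrna_hc_init(fc);

  std::vector<char> incident(n + 1, 0);
  std::vector<std::pair<int, int> > allowed;
  for (int k = 0; k < pairs.nrow(); ++k) {
    int i = pairs(k, 0), j = pairs(k, 1);
    if (i < 1 || j > n || i >= j)
      { vrna_fold_compound_free(fc); stop("invalid pair in union set"); }
    incident[i] = incident[j] = 1;
    allowed.push_back(std::make_pair(i, j));
  }
  // positions touched by no allowed pair must stay unpaired
  for (int i = 1; i <= n; ++i)
    if (!incident[i])
      vrna_hc_add_up(fc, i, VRNA_CONSTRAINT_CONTEXT_ALL_LOOPS);
  // forbid any other pairing among the incident positions
  std::vector<int> inc;
  for (int i = 1; i <= n; ++i) if (incident[i]) inc.push_back(i);
  for (size_t a = 0; a < inc.size(); ++a) {
    for (size_t b = a + 1; b < inc.size(); ++b) {
      int i = inc[a], j = inc[b];
      if (j - i <= 3) continue;
      if (!ctf_canonical_pair(seq[i - 1], seq[j - 1])) continue;
      bool ok = false;
      for (size_t k = 0; k < allowed.size(); ++k)
        if (allowed[k].first == i && allowed[k].second == j) { ok = true; break; }
      if (!ok)
        vrna_hc_add_bp(fc, i, j,
                       VRNA_CONSTRAINT_CONTEXT_NONE |
                       VRNA_CONSTRAINT_CONTEXT_NO_REMOVE);
    }
  }

  std::vector<char> ss(seq.size() + 1, 0);
  float e = vrna_mfe(fc, ss.data());
  vrna_fold_compound_free(fc);
  return List::create(_["structure"] = std::string(ss.data()),
                      _["energy"] = (double) e,
                      _["feasible"] = (bool) (R_finite(e) && e < 1e4));
}
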