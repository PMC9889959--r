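#include <Rcpp.h>
#include <random>
#include <unordered_map>
#include "vrna_common.h"

using namespace Rcpp;

namespace {

struct MoveSet {
  std::vector<int> m1, m2;     // signed positions: positive close, negative open
  std::vector<double> rate;
  double total;
};

const double GASCONST_KCAL = 0.00198717;

}  // namespace

// Stochastic cotranscriptional folding with single base-pair moves and
// Metropolis rates k = k0 * min(1, exp(-dE/RT)); the independent reference
// simulator for the deterministic pipeline. The chain starts unpaired at
// `start_length`; `step_times[k]` is the time spent at transcript length
// start_length + k before the next nucleotide appears, and `t_end` is the
// post-transcriptional simulation time. Energies are evaluated at full
// length (unpaired 3' tail), matching the deterministic pipeline.
// Returns the final structure of each trajectory.
// [[Rcpp::export]]
CharacterVector cpp_gillespie(std::string seq,
                              int start_length,
                              NumericVector step_times,
                              double t_end,
                              double k0,
                              double temperature,
                              bool noLP,
                              int n_traj,
                              int seed) {
  int n = (int) seq.size();
  if (start_length < 1 || start_length > n) stop("invalid start_length");
  if ((int) step_times.size() != n - start_length)
    stop("step_times must have length L - start_length");

  vrna_md_t md = ctf_model_details(temperature, noLP);
  vrna_fold_compound_t *fc =
      vrna_fold_compound(seq.c_str(), &md, VRNA_OPTION_EVAL_ONLY);
  const double RT = GASCONST_KCAL * (temperature + 273.15);

  // all base pairs permitted by the structure definition
  std::vector<std::pair<int, int> > allowed;
  for (int i = 1; i <= n; ++i)
    for (int j = i + 4; j <= n; ++j)
      if (ctf_canonical_pair(seq[i - 1], seq[j - 1]))
        allowed.push_back(std::make_pair(i, j));

  // move sets cached per (transcript length, structure)
  std::vector<std::unordered_map<std::string, MoveSet> > cache(n + 1);

  auto moves_for = [&](const std::vector<short> &pt, int l) -> const MoveSet & {
    std::string key = ctf_db_from_pt(pt);
    auto &tab = cache[l];
    auto it = tab.find(key);
    if (it != tab.end()) return it->second;
    MoveSet ms;
    ms.total = 0.0;
    // openings
    for (int i = 1; i <= l; ++i) {
      if (pt[i] > i) {
        int dE = vrna_eval_move_pt(fc, const_cast<short *>(pt.data()), -i, -(int) pt[i]);
        double k = k0 * std::min(1.0, std::exp(-(dE / 100.0) / RT));
        ms.m1.push_back(-i); ms.m2.push_back(-(int) pt[i]);
        ms.rate.push_back(k); ms.total += k;
      }
    }
    // closings
    for (size_t a = 0; a < allowed.size(); ++a) {
      int i = allowed[a].first, j = allowed[a].second;
      if (j > l) continue;
      if (pt[i] != 0 || pt[j] != 0) continue;
      bool cross = false;
      for (int k = i + 1; k < j && !cross; ++k)
        if (pt[k] != 0 && (pt[k] < i || pt[k] > j)) cross = true;
      if (cross) continue;
      int dE = vrna_eval_move_pt(fc, const_cast<short *>(pt.data()), i, j);
      double k = k0 * std::min(1.0, std::exp(-(dE / 100.0) / RT));
      ms.m1.push_back(i); ms.m2.push_back(j);
      ms.rate.push_back(k); ms.total += k;
    }
    auto res = tab.emplace(std::move(key), std::move(ms));
    return res.first->second;
  };

  CharacterVector finals(n_traj);

  for (int traj = 0; traj < n_traj; ++traj) {
    std::mt19937_64 rng(1000003ULL * (unsigned long long) seed +
                        (unsigned long long) traj);
    std::uniform_real_distribution<double> unif(
        std::numeric_limits<double>::min(), 1.0);

    std::vector<short> pt(n + 1, 0);
    pt[0] = (short) n;

    int n_windows = (int) step_times.size() + 1;
    for (int w = 0; w < n_windows; ++w) {
      int l = start_length + w;
      if (l > n) l = n;
      double tw = (w < (int) step_times.size()) ? step_times[w] : t_end;
      double t = 0.0;
      while (true) {
        const MoveSet &ms = moves_for(pt, l);
        if (ms.total <= 0.0) break;
        double dt = -std::log(unif(rng)) / ms.total;
        if (t + dt >= tw) break;
        t += dt;
        double u = unif(rng) * ms.total, acc = 0.0;
        size_t pick = ms.rate.size() - 1;
        for (size_t m = 0; m < ms.rate.size(); ++m) {
          acc += ms.rate[m];
          if (u <= acc) { pick = m; break; }
        }
        int m1 = ms.m1[pick], m2 = ms.m2[pick];
        if (m1 > 0) { pt[m1] = (short) m2; pt[m2] = (short) m1; }
        else        { pt[-m1] = 0; pt[-m2] = 0; }
      }
    }
    finals[traj] = ctf_db_from_pt(pt);
  }

  vrna_fold_compound_free(fc);
  return finals;
}
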