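#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <unordered_map>
#include "vrna_common.h"

using namespace Rcpp;

namespace {

struct Move {
  int i, j;
  bool close;  // true: insert pair, false: delete pair
};

struct State {
  std::vector<short> pt;
  int energy;             // dcal/mol
  int saddle;             // dcal/mol, max energy on partial path
  std::vector<int> applied;  // move indices in application order
};

bool close_valid(const std::vector<short> &pt, int i, int j) {
  if (pt[i] != 0 || pt[j] != 0) return false;
  for (int k = i + 1; k < j; ++k)
    if (pt[k] != 0 && (pt[k] < i || pt[k] > j)) return false;
  return true;
}

// one beam-search pass; children with saddle > bound are discarded
// (the caller already holds a complete path at `bound`)
bool beam_pass(vrna_fold_compound_t *fc,
               const std::vector<Move> &moves,
               const State &start,
               int width,
               int bound,
               State &result) {
  int d = (int) moves.size();
  std::vector<State> beam;
  beam.push_back(start);
  for (int level = 0; level < d; ++level) {
    struct Child {
      int parent;
      int move;
      int energy;
      int saddle;
    };
    std::vector<Child> children;
    // dedup on the set of applied moves: the same set means the same
    // structure (and energy); keep the parent with the smaller saddle
    std::unordered_map<std::string, int> best;  // key -> index in children
    for (size_t sidx = 0; sidx < beam.size(); ++sidx) {
      const State &s = beam[sidx];
      std::vector<char> used(d, '0');
      for (int m : s.applied) used[m] = '1';
      for (int m = 0; m < d; ++m) {
        if (used[m] == '1') continue;
        const Move &mv = moves[m];
        if (mv.close) {
          if (!close_valid(s.pt, mv.i, mv.j)) continue;
        } else {
          if (s.pt[mv.i] != mv.j) continue;
        }
        used[m] = '1';
        std::string key(used.begin(), used.end());
        used[m] = '0';
        auto it = best.find(key);
        if (it != best.end()) {
          // same child structure seen: only the saddle can improve
          Child &c = children[it->second];
          int sad = std::max(s.saddle, c.energy);
          if (sad < c.saddle) {
            c.saddle = sad;
            c.parent = (int) sidx;
            c.move = m;
          }
          continue;
        }
        int m1 = mv.close ? mv.i : -mv.i;
        int m2 = mv.close ? mv.j : -mv.j;
        int dE = vrna_eval_move_pt(fc, const_cast<short *>(s.pt.data()),
                                   m1, m2);
        int e = s.energy + dE;
        int sad = std::max(s.saddle, e);
        if (sad > bound) continue;
        Child c;
        c.parent = (int) sidx;
        c.move = m;
        c.energy = e;
        c.saddle = sad;
        best[key] = (int) children.size();
        children.push_back(c);
      }
    }
    if (children.empty()) return false;
    std::vector<int> order(children.size());
    for (size_t k = 0; k < order.size(); ++k) order[k] = (int) k;
    std::sort(order.begin(), order.end(), [&](int a, int b) {
      if (children[a].saddle != children[b].saddle)
        return children[a].saddle < children[b].saddle;
      if (children[a].energy != children[b].energy)
        return children[a].energy < children[b].energy;
      const Child &ca = children[a], &cb = children[b];
      if (beam[ca.parent].applied != beam[cb.parent].applied)
        return beam[ca.parent].applied < beam[cb.parent].applied;
      return ca.move < cb.move;
    });
    if ((int) order.size() > width) order.resize(width);
    std::vector<State> next;
    next.reserve(order.size());
    for (int oi : order) {
      const Child &c = children[oi];
      const State &p = beam[c.parent];
      State s;
      s.pt = p.pt;
      const Move &mv = moves[c.move];
      if (mv.close) { s.pt[mv.i] = (short) mv.j; s.pt[mv.j] = (short) mv.i; }
      else          { s.pt[mv.i] = 0; s.pt[mv.j] = 0; }
      s.energy = c.energy;
      s.saddle = c.saddle;
      s.applied = p.applied;
      s.applied.push_back(c.move);
      next.push_back(std::move(s));
    }
    beam = std::move(next);
  }
  result = beam.front();
  return true;
}

}  // namespace

// Direct-path search between two structures on the same sequence: a beam
// search over move orderings that keeps the `width` partial paths with the
// lowest saddle energy. A width-1 greedy pass first establishes a saddle
// bound which prunes the full-width pass. Consecutive path steps differ by
// one base pair and the path has length d(x, y). Deterministic for fixed
// width.
// [[Rcpp::export]]
List cpp_findpath(std::string seq,
                  std::string x,
                  std::string y,
                  int width,
                  double temperature,
                  bool noLP) {
  int n = (int) seq.size();
  if ((int) x.size() != n || (int) y.size() != n)
    stop("structures must match sequence length");
  if (width < 1) width = 1;

  vrna_md_t md = ctf_model_details(temperature, noLP);
  vrna_fold_compound_t *fc =
      vrna_fold_compound(seq.c_str(), &md, VRNA_OPTION_EVAL_ONLY);

  std::vector<short> ptx = ctf_pair_table(x);
  std::vector<short> pty = ctf_pair_table(y);

  std::vector<Move> moves;
  for (int i = 1; i <= n; ++i) {
    if (ptx[i] > i && pty[i] != ptx[i]) moves.push_back({i, ptx[i], false});
    if (pty[i] > i && ptx[i] != pty[i]) moves.push_back({i, pty[i], true});
  }
  std::sort(moves.begin(), moves.end(), [](const Move &a, const Move &b) {
    if (a.i != b.i) return a.i < b.i;
    if (a.j != b.j) return a.j < b.j;
    return a.close < b.close;
  });
  int d = (int) moves.size();

  int e0 = vrna_eval_structure_pt(fc, ptx.data());
  State start;
  start.pt = ptx;
  start.energy = e0;
  start.saddle = e0;

  // opening all of x's moves first always yields a valid direct path, so the
  // greedy pass cannot stall with an infinite bound
  State greedy;
  bool ok = beam_pass(fc, moves, start, 1, INT_MAX, greedy);
  if (!ok) { vrna_fold_compound_free(fc); stop("direct path search stalled"); }
  State bestState = greedy;
  if (width > 1 && d > 1) {
    State refined;
    if (beam_pass(fc, moves, start, width, bestState.saddle, refined)) {
      if (refined.saddle < bestState.saddle ||
          (refined.saddle == bestState.saddle &&
           refined.applied < bestState.applied))
        bestState = refined;
    }
  }

  // replay the winning move order to emit the path
  CharacterVector steps(d + 1);
  NumericVector energies(d + 1);
  std::vector<short> pt = ptx;
  int e = e0;
  steps[0] = ctf_db_from_pt(pt);
  energies[0] = e0 / 100.0;
  for (int k = 0; k < d; ++k) {
    const Move &mv = moves[bestState.applied[k]];
    int m1 = mv.close ? mv.i : -mv.i;
    int m2 = mv.close ? mv.j : -mv.j;
    e += vrna_eval_move_pt(fc, pt.data(), m1, m2);
    if (mv.close) { pt[mv.i] = (short) mv.j; pt[mv.j] = (short) mv.i; }
    else          { pt[mv.i] = 0; pt[mv.j] = 0; }
    steps[k + 1] = ctf_db_from_pt(pt);
    energies[k + 1] = e / 100.0;
  }
  vrna_fold_compound_free(fc);

  return List::create(_["steps"] = steps,
                      _["energies"] = energies,
                      _["width"] = width);
}
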