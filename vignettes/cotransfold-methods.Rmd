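---
title: "Cotranscriptional folding kinetics: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cotranscriptional folding kinetics: model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoTransFold)
```

## The problem

RNA molecules fold while they are transcribed. Because the polymerase adds
nucleotides at 20–200 nt/s, 5' regions can settle into metastable helices
long before potentially stronger 3' partners exist, so the ensemble observed
at the end of transcription can differ drastically from the thermodynamic
equilibrium ensemble. Stochastic simulators that walk the full elementary
move set (single base-pair openings and closings) are statistically exact but
require thousands of trajectories and scale poorly beyond ~100 nt.
`CoTransFold` implements a deterministic heuristic for this process: it
maintains a small, adaptively grown set of candidate secondary structures, a
graph of reactions between them with saddle energies, and integrates a master
equation for the occupancies between nucleotide additions.

## One transcription step

For every new nucleotide the simulator runs four phases.

**Expansion.** Each parent structure (survivor of the previous step) is
extended by an unpaired nucleotide. New candidates are generated by
constrained minimum-free-energy folding in which all base pairs and loop
regions are fixed except the exterior loop and the *fraying* helices adjacent
to it: each fraying helix is opened separately, and all of them at once; if
opening a helix liberates fewer than `mfree` (default 6) nucleotides the next
enclosed helices are opened too. A constrained fold result is kept when its
energy is at or below its parent's (tolerance 0.01 kcal/mol, one energy
parameter quantum). The unconstrained MFE structure of the current transcript
is always added. Only the exterior loop can accept the new 3' nucleotide
without forming a pseudoknot, which is why the search is local in exactly
this sense.

**Guiding neighborhood.** Reactions are postulated between candidates using
base-pair distances only: `x` and `y` are guide neighbors unless some
candidate `i` lies strictly between them (`max(d(x,i), d(i,y)) < d(x,y)`);
shortcut edges additionally connect guide neighbors `x, y` of `i` when `i`
is not on a direct path between them (`d(x,i) + d(i,y) > d(x,y)`). For every
edge, the MFE structure restricted to the union of the endpoints' pairs is
computed; new structures found this way re-trigger the construction. In the
limit of the complete structure ensemble this graph reduces to the elementary
move set (a property the test suite checks on sequences up to 10 nt).

**Rates.** For each new edge a direct refolding path (length `d(x,y)`, one
base-pair change per step) with low saddle energy is sought with a beam
search over move orderings; a width-1 greedy pass provides an upper bound
that prunes the full-width pass, which makes the search deterministic and
fast without changing its result. The path's energy profile is *flooded*:
an interior step is a delta-minimum if every escape to a strictly lower
energy crosses a barrier of at least `delta`. If no interior delta-minimum
lies at or below the higher endpoint, the transition is direct and its rate
follows the Arrhenius law `k = k0 * exp(-(E_saddle - E_x)/RT)`; for a single
base-pair move this is exactly the Metropolis rule. Otherwise the qualifying
minima become candidates themselves and the flanking subpaths are re-searched
(with doubled beam width) and decomposed recursively. Reactions are cached
across transcription steps — energies are always evaluated at the full
transcript length (assuming an unpaired 3' tail), so a stored energy or
saddle never changes retroactively. This full-length convention trades a
small dangling-end inaccuracy for the ability to reuse all previous work.

**Coarse graining.** Candidates are processed from high to low energy. A
structure with a reaction to an equal-or-lower-energy neighbor whose saddle
lies below `E + delta` is *transient*: its occupancy is split equally among
its minimal-saddle neighbors, every neighbor reachable by such a fast
reaction is connected to all other neighbors (two neighbors reachable only
by slow reactions are not connected), and new edges inherit the larger of
the two saddles through the removed node, keeping the minimum over duplicate
edges. The survivors are the delta-minimum representatives. Occupancy is
conserved exactly (to 1e-12 in the tests).

**Kinetics.** Representative reactions define a column generator
`R[j,i] = k(i->j)`, `R[i,i] = -sum_j k(i->j)`. Because all rates derive from
shared saddles, detailed balance holds by construction and the stationary
distribution is the Boltzmann distribution over representatives. The
propagator `exp(Rt)` is evaluated by symmetrizing `U = D^-1 R D` with
`D = diag(sqrt(p_inf))` and eigendecomposing once; all time points then cost
a diagonal exponential. (With `D = diag(p_inf)` the similarity transform is
not symmetric under detailed balance; the square-root form is.) A Padé
matrix exponential serves as fallback and as an independent cross-check in
the tests (agreement to 1e-8 on random 10-state systems). Each step
simulates a linear regime `[0, t1]` — the extension interval, 10 points —
and a logarithmic *look-ahead* regime `(t1, t8]` (30 points per decade)
reaching to the projected end of transcription,
`t8 = sum of remaining extension times` (including pauses), or to `tEnd`
after the last nucleotide.

**Pruning.** A representative whose occupancy stays below the threshold `o`
(default 0.05) at every look-ahead time point is prunable; structures that
transiently exceed `o` are exempt because they become relevant later.
Prunable structures are removed in ascending occupancy order while the
cumulative removed occupancy stays strictly below `o`, which guarantees the
surviving parents carry at least `1 - o`. Removed occupancy is redistributed
*lazily*: a pruned structure re-discovered as a candidate in the next
expansion keeps its occupancy; otherwise it is split evenly among the
nearest surviving structures in the reaction graph of the pruning step
(breadth-first, so neighbors of neighbors receive it when all direct
neighbors were pruned too).

## Parameters

| parameter | unit | default | meaning |
|---|---|---|---|
| `tExt` | s/nt | 0.04 | extension time (25 nt/s) |
| `tEnd` | s | 60 | post-transcriptional simulation time |
| `k0` | 1/s | 1e5 | Arrhenius pre-exponential constant |
| `delta` | kcal/mol | `RT*log(k0*tExt)` (~5.1) | coarse-graining barrier |
| `oPrune` | – | 0.05 | max occupancy discarded per step |
| `mfree` | nt | 6 | minimum liberated nucleotides per fraying constraint |
| `temperature` | °C | 37 | passed to the energy model |
| `fpWidthFactor` | – | 4 | beam width = factor × distance |
| `fpWidthMax` | – | 8 | beam width cap inside the transcription loop |

The default `delta` classifies a reaction as fast when its Arrhenius rate
reaches at least `1/tExt`, i.e. when it can act within one extension
interval; this ties the coarse-graining strength to the timescale separation
that justifies it. `k0` and the times are redundant by design: doubling `k0`
and halving all times yields identical trajectories on a rescaled clock
(verified in the tests). The beam-width cap bounds the per-edge cost of the
direct-path search, which otherwise grows cubically with the base-pair
distance; with the greedy bound in place, widening the beam beyond the cap
changed no saddle in the cases we examined, but the cap is exposed so users
can raise it.

## Numerical choices

* Energies are handled in kcal/mol as returned by the nearest-neighbor
  engine (0.01 kcal/mol resolution); "energetically equivalent or better"
  uses a 0.01 kcal/mol tolerance.
* Ties are broken lexicographically on dot-bracket strings everywhere a
  processing order matters (coarse-graining order at equal energy, pruning
  order at equal occupancy, beam ranking), making runs bit-reproducible.
* The transient test compares neighbor energies non-strictly (`<=`), reading
  the coarse-graining rule literally; at exact energy ties this deliberately
  merges more aggressively than the strict delta-minimum definition. The
  equivalence tests against the brute-force definition therefore use
  continuous (tie-free) energies.
* Path flooding never merges path endpoints — they are externally supplied
  candidates; endpoints are reported as minima regardless of `delta`.
* Occupancies below 1e-16 are clipped to zero and every propagated vector is
  renormalized; a detailed-balance violation in the rate matrix raises an
  error instead of being patched over, because it signals an upstream bug.
* An enforced constraint that the engine cannot satisfy (it silently drops
  impossible pairs) is detected by re-checking the returned structure and
  reported as infeasible.

## The stochastic reference simulator

`gillespieFold()` implements the presumed ground-truth model: a continuous
time Monte Carlo walk over single base-pair moves with Metropolis rates and
the same transcription schedule and full-length energy convention as the
deterministic pipeline. It exists for validation, not production; move sets
are cached per (structure, transcript length), which keeps 1e4 trajectories
of a 25-nt sequence in the seconds range. During development it was checked
against an exact master equation on a fully enumerated 84-structure ensemble.

## What the validation does and does not show

The test suite validates the pieces against independent oracles: exhaustive
direct-path enumeration, sub-interval enumeration for flooding, minimax
(widest-path) searches for graph coarse graining, subset enumeration for the
union-constrained MFE, closed-form and Padé solutions for the kinetics, and
the stochastic simulator for end-to-end behavior. Random sequences are
uniform over ACGU — they lack the base composition bias, conserved helices
and modified nucleotides of natural RNAs, so passing tests demonstrate
algorithmic correctness, not biological accuracy.

End-to-end, the deterministic heuristic reproduces the stochastic reference
qualitatively (same dominant basins, same direction of kinetic trapping),
but not to statistical sampling precision: single-saddle Arrhenius rates for
multi-step refolding ignore path multiplicity and commitment probabilities,
the candidate set is sparse (a competing helix that is never the MFE of any
transcript prefix and shares no pairs with one can be missed entirely), and
representative free energies ignore the entropy of the basin they stand for.
The acceptance suite contains a deliberately strict comparison (3 standard
errors of a 1e4-trajectory estimate) on five bistable switches that
documents this gap rather than hiding it; quantitative agreement at that
tolerance is beyond the method by design.

## Scale of the shipped experiments

The MFE-fraction experiments run 100 random 60-nt sequences (inspected
0.04 s after transcription) and 30 random 200-nt sequences (inspected after
3600 s of simulated post-transcriptional time). The oracle comparisons use
sequences of at most 25 nt with 1e4 trajectories, and the property suites
use 1e3 random landscapes/profiles per invariant. These sizes were chosen so
the full suite runs in well under half an hour on one core while every
statistical check retains enough power to fail loudly when a regression is
introduced.
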