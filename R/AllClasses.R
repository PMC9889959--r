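# gas constant in kcal/(mol K)
.RGAS <- 0.00198717

.rt <- function(temperatureC) .RGAS * (temperatureC + 273.15)

#' Energy model classes
#'
#' `EnergyModel` is the virtual adapter contract to a nearest-neighbor
#' thermodynamics engine: deterministic free energies in kcal/mol and
#' constrained MFE folding, with energies always evaluated at the full
#' transcript length (unpaired 3' tail). Two backends ship with the package:
#'
#' * `ViennaEnergyModel` — the production backend; links the ViennaRNA
#'   (RNAlib) nearest-neighbor implementation.
#' * `ToyEnergyModel` — a deterministic, additive pair/stack energy table,
#'   used for engine-light unit testing of the landscape algorithms. Its
#'   folding operations enumerate the structure space exhaustively and are
#'   only meant for short sequences.
#'
#' @slot temperature temperature in degrees Celsius.
#' @slot noLP logical; disallow lonely (unstacked) pairs in folding
#'   (pass-through to the engine; default `FALSE`).
#' @slot pairEnergies named numeric, kcal/mol per pair type (toy backend).
#' @slot stackBonus numeric, kcal/mol per stacked adjacent pair (toy backend).
#' @aliases ViennaEnergyModel-class ToyEnergyModel-class
#' @name EnergyModel-class
#' @exportClass EnergyModel ViennaEnergyModel ToyEnergyModel
setClass("EnergyModel", representation("VIRTUAL",
  temperature = "numeric"))

setClass("ViennaEnergyModel", contains = "EnergyModel",
  representation(noLP = "logical"),
  prototype(temperature = 37, noLP = FALSE))

setClass("ToyEnergyModel", contains = "EnergyModel",
  representation(pairEnergies = "numeric", stackBonus = "numeric"),
  prototype(temperature = 37,
            pairEnergies = c(GC = -2.1, CG = -2.1, AU = -1.1, UA = -1.1,
                             GU = -0.5, UG = -0.5),
            stackBonus = -1.0))

setValidity("EnergyModel", function(object) {
  if (length(object@temperature) != 1L || !is.finite(object@temperature))
    return("temperature must be a single finite number (Celsius)")
  TRUE
})

#' Construct the ViennaRNA-backed energy model
#'
#' @param temperature folding temperature in degrees Celsius.
#' @param noLP disallow lonely pairs (engine pass-through).
#' @return a `ViennaEnergyModel` object.
#' @examples
#' m <- viennaModel()
#' freeEnergy(m, "GGGAAACCC", "(((...)))")
#' @export
viennaModel <- function(temperature = 37, noLP = FALSE)
  new("ViennaEnergyModel", temperature = temperature, noLP = noLP)

#' Construct the additive toy energy model
#'
#' @param temperature nominal temperature in degrees Celsius (used for rates).
#' @param pairEnergies named numeric vector of per-pair energies (kcal/mol).
#' @param stackBonus energy bonus per stacked adjacent pair (kcal/mol).
#' @return a `ToyEnergyModel` object.
#' @export
toyModel <- function(temperature = 37,
                     pairEnergies = c(GC = -2.1, CG = -2.1, AU = -1.1,
                                      UA = -1.1, GU = -0.5, UG = -0.5),
                     stackBonus = -1.0)
  new("ToyEnergyModel", temperature = temperature,
      pairEnergies = pairEnergies, stackBonus = stackBonus)

#' Direct refolding path between two structures
#'
#' An ordered list of structures from `x` to `y` in which consecutive
#' structures differ by exactly one base pair, together with per-step free
#' energies; the number of steps is `d(x, y) + 1`.
#'
#' @slot steps character vector of dot-bracket structures.
#' @slot energies numeric vector of free energies (kcal/mol), same length.
#' @slot width beam width used by the search.
#' @export
setClass("DirectPath", representation(
  steps = "character", energies = "numeric", width = "integer"))

setValidity("DirectPath", function(object) {
  if (length(object@steps) != length(object@energies))
    return("steps and energies differ in length")
  if (length(object@steps) < 1L) return("empty path")
  TRUE
})

#' Result of flooding a one-dimensional energy profile
#'
#' @slot minima integer indices (1-based) of the path endpoints and interior
#'   delta-minima, in path order.
#' @slot minimaEnergies energies of those minima.
#' @slot saddles data.frame with one row per adjacent pair of minima:
#'   `from`, `to` (indices into the profile), `at` (index of the maximal
#'   intervening energy) and `energy`.
#' @export
setClass("FloodResult", representation(
  minima = "integer", minimaEnergies = "numeric", saddles = "data.frame"))

#' Sparse energy landscape of candidate structures
#'
#' A strongly connected graph whose nodes are secondary structures (with free
#' energy and occupancy) and whose edges are reversible candidate reactions
#' carrying saddle energies. Saddles satisfy `E_saddle >= max(E_x, E_y)` and
#' rates derived from them obey detailed balance by construction.
#'
#' @slot sequence full-length RNA sequence.
#' @slot transcriptLength current transcript length.
#' @slot nodes data.frame: `structure`, `energy`, `occupancy`.
#' @slot edges data.frame: `from`, `to` (structures), `saddle` (kcal/mol).
#' @slot cache environment holding the persistent energy/reaction caches.
#' @export
setClass("Landscape", representation(
  sequence = "character", transcriptLength = "integer",
  nodes = "data.frame", edges = "data.frame", cache = "environment"))

setValidity("Landscape", function(object) {
  nd <- object@nodes
  ed <- object@edges
  if (nrow(nd) && anyDuplicated(nd$structure))
    return("duplicate structures among nodes")
  if (nrow(ed)) {
    en <- setNames(nd$energy, nd$structure)
    bad <- ed$saddle + 1e-6 < pmax(en[ed$from], en[ed$to])
    if (any(bad)) return("edge saddle below endpoint energy")
  }
  TRUE
})

#' @rdname Landscape-class
#' @param x a `Landscape` (or `CoarseLandscape`).
#' @export
setMethod("landscapeNodes", "Landscape", function(x) x@nodes)

#' @rdname Landscape-class
#' @export
setMethod("landscapeEdges", "Landscape", function(x) x@edges)

#' Coarse-grained landscape of delta-minimum representatives
#'
#' Result of the top-down coarse graining: a subset of the landscape nodes
#' (the delta-minima) with representative reactions whose saddles are minimal
#' over all merged candidate reactions, plus the mapping that records where
#' the occupancy of each transient structure went.
#'
#' @slot nodes data.frame of representatives: `structure`, `energy`,
#'   `occupancy`.
#' @slot edges data.frame: `from`, `to`, `saddle`.
#' @slot basinMap named list: transient structure -> data.frame
#'   (`structure`, `weight`) over representatives.
#' @slot delta coarse-graining barrier threshold (kcal/mol).
#' @export
setClass("CoarseLandscape", representation(
  nodes = "data.frame", edges = "data.frame", basinMap = "list",
  delta = "numeric"))

#' @rdname CoarseLandscape-class
#' @param x a `CoarseLandscape`.
#' @export
setMethod("representatives", "CoarseLandscape", function(x) x@nodes)

setMethod("landscapeNodes", "CoarseLandscape", function(x) x@nodes)
setMethod("landscapeEdges", "CoarseLandscape", function(x) x@edges)

#' Simulation time grid
#'
#' Every per-nucleotide simulation has a linear regime `[t0, t1]` (the
#' extension interval) and a logarithmic regime `(t1, t8]` (the look-ahead
#' until the projected end of transcription, or the post-transcriptional
#' time after the last nucleotide).
#'
#' @slot t0,t1,t8 regime boundaries in seconds; `t0 < t1 <= t8`.
#' @slot linearPoints number of points in the linear regime.
#' @slot logPerDecade number of geometrically spaced points per decade.
#' @export
setClass("TimeGrid", representation(
  t0 = "numeric", t1 = "numeric", t8 = "numeric",
  linearPoints = "integer", logPerDecade = "integer"),
  prototype(t0 = 0, linearPoints = 10L, logPerDecade = 30L))

setValidity("TimeGrid", function(object) {
  if (!(object@t0 < object@t1 && object@t1 <= object@t8))
    return("need t0 < t1 <= t8")
  TRUE
})

#' Report of one pruning round
#'
#' @slot parents data.frame of surviving representatives (`structure`,
#'   `energy`, `occupancy`); their combined occupancy is at least `1 - o`.
#' @slot pruned data.frame of removed structures with their occupancies.
#' @slot graph data.frame of landscape edges at pruning time (used for the
#'   deferred occupancy redistribution).
#' @slot threshold the occupancy threshold `o`.
#' @export
setClass("PruneReport", representation(
  parents = "data.frame", pruned = "data.frame", graph = "data.frame",
  threshold = "numeric"))

#' Simulation configuration
#'
#' Bundles the tunable parameters of the transcription loop.
#'
#' @slot tExt extension time per nucleotide in seconds (default 0.04 s,
#'   i.e. 25 nt/s).
#' @slot tEnd post-transcriptional simulation time in seconds (default 60).
#' @slot k0 Arrhenius pre-exponential rate constant in 1/s (default 1e5).
#' @slot delta coarse-graining barrier threshold in kcal/mol; `NA` selects
#'   the default `RT * log(k0 * tExt)`, the largest barrier whose Arrhenius
#'   rate still reaches `1/tExt` (reactions faster than the extension
#'   interval are treated as fast).
#' @slot oPrune occupancy threshold `o`: the maximum total occupancy that may
#'   be discarded per transcription step (default 0.05).
#' @slot mfree minimum number of nucleotides a fraying constraint must
#'   liberate before deeper helices are opened as well (default 6).
#' @slot temperature degrees Celsius (default 37).
#' @slot noLP disallow lonely pairs (default `FALSE`).
#' @slot pauseSites named numeric vector: position -> extra seconds spent at
#'   that transcript length.
#' @slot startLength transcript length at which the simulation starts.
#' @slot fpWidthFactor beam width of the direct-path search as a multiple of
#'   the base-pair distance (default 4; doubled when subpaths are re-searched).
#' @slot fpWidthMax upper bound on the beam width used inside the
#'   transcription loop (default 8); keeps the per-edge search cost bounded
#'   for distant structure pairs.
#' @export
setClass("SimulationConfig", representation(
  tExt = "numeric", tEnd = "numeric", k0 = "numeric", delta = "numeric",
  oPrune = "numeric", mfree = "integer", temperature = "numeric",
  noLP = "logical", pauseSites = "numeric", startLength = "integer",
  fpWidthFactor = "numeric", fpWidthMax = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@tExt <= 0) return("tExt must be positive")
  if (object@tEnd <= 0) return("tEnd must be positive")
  if (object@k0 <= 0) return("k0 must be positive")
  if (!is.na(object@delta) && object@delta <= 0)
    return("delta must be positive")
  if (object@oPrune < 0 || object@oPrune >= 1)
    return("oPrune must be in [0, 1)")
  if (object@mfree < 0L) return("mfree must be non-negative")
  if (object@startLength < 1L) return("startLength must be >= 1")
  if (length(object@pauseSites) &&
      (is.null(names(object@pauseSites)) || any(object@pauseSites < 0)))
    return("pauseSites must be a named vector of non-negative extra seconds")
  TRUE
})

#' Create a simulation configuration
#'
#' @param tExt,tEnd,k0,delta,oPrune,mfree,temperature,noLP,pauseSites,startLength,fpWidthFactor,fpWidthMax
#'   see [SimulationConfig-class].
#' @return a validated `SimulationConfig`.
#' @examples
#' simConfig(tExt = 0.02, tEnd = 10)
#' @export
simConfig <- function(tExt = 0.04, tEnd = 60, k0 = 1e5, delta = NA_real_,
                      oPrune = 0.05, mfree = 6L, temperature = 37,
                      noLP = FALSE, pauseSites = numeric(0),
                      startLength = 1L, fpWidthFactor = 4,
                      fpWidthMax = 8L) {
  new("SimulationConfig", tExt = tExt, tEnd = tEnd, k0 = k0,
      delta = as.numeric(delta), oPrune = oPrune, mfree = as.integer(mfree),
      temperature = temperature, noLP = noLP, pauseSites = pauseSites,
      startLength = as.integer(startLength), fpWidthFactor = fpWidthFactor,
      fpWidthMax = as.integer(fpWidthMax))
}

# resolved coarse-graining threshold (kcal/mol)
configDelta <- function(config) {
  if (!is.na(config@delta)) return(config@delta)
  .rt(config@temperature) * log(config@k0 * config@tExt)
}

#' Result of a cotranscriptional folding simulation
#'
#' @slot sequence the simulated sequence.
#' @slot config the [SimulationConfig-class] used.
#' @slot trajectory data.frame with columns `length`, `time_s` (global
#'   simulation time in seconds), `id` (stable structure id), `structure`,
#'   `energy_kcal` and `occupancy`; occupancies within each (length, time)
#'   block sum to one.
#' @slot stats per-step diagnostics: number of candidates, representatives,
#'   edges, pruned structures.
#' @export
setClass("TrajectoryResult", representation(
  sequence = "character", config = "SimulationConfig",
  trajectory = "data.frame", stats = "data.frame"))

#' @rdname TrajectoryResult-class
#' @export
setMethod("trajectory", "TrajectoryResult", function(x) x@trajectory)

#' @rdname TrajectoryResult-class
#' @export
setMethod("finalOccupancies", "TrajectoryResult", function(x) {
  tr <- x@trajectory
  last <- tr[tr$time_s == max(tr$time_s), , drop = FALSE]
  last <- last[order(-last$occupancy, last$structure), , drop = FALSE]
  rownames(last) <- NULL
  last[, c("id", "structure", "energy_kcal", "occupancy")]
})

#' @rdname TrajectoryResult-class
#' @export
setMethod("stepStats", "TrajectoryResult", function(x) x@stats)

setMethod("show", "TrajectoryResult", function(object) {
  tr <- object@trajectory
  cat("TrajectoryResult:", nchar(object@sequence), "nt,",
      nrow(tr), "trajectory rows\n")
  fo <- finalOccupancies(object)
  cat("final ensemble (t =", format(max(tr$time_s)), "s):\n")
  print(head(fo, 5), row.names = FALSE)
  invisible(object)
})

setMethod("show", "Landscape", function(object) {
  cat("Landscape at transcript length", object@transcriptLength, "of",
      nchar(object@sequence), "nt:", nrow(object@nodes), "structures,",
      nrow(object@edges), "reversible reactions\n")
  invisible(object)
})

setMethod("show", "CoarseLandscape", function(object) {
  cat("CoarseLandscape (delta =", format(object@delta), "kcal/mol):",
      nrow(object@nodes), "representatives,", nrow(object@edges),
      "transitions,", length(object@basinMap), "transients\n")
  invisible(object)
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: tExt =", object@tExt, "s/nt, tEnd =", object@tEnd,
      "s, k0 =", format(object@k0), "/s, delta =",
      format(configDelta(object)), "kcal/mol, oPrune =", object@oPrune,
      ", mfree =", object@mfree, ", T =", object@temperature, "C\n")
  invisible(object)
})

setMethod("show", "DirectPath", function(object) {
  cat("DirectPath:", length(object@steps), "steps, saddle =",
      format(max(object@energies)), "kcal/mol\n")
  invisible(object)
})
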