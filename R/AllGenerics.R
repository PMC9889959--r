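#' @useDynLib CoTransFold, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is show slot
#' @importFrom stats setNames rexp runif
#' @importFrom utils head read.delim write.table
NULL

#' Free energy of secondary structures
#'
#' Evaluates the nearest-neighbor free energy of one or more structures on a
#' sequence. Structures shorter than the full sequence are treated as having
#' an unpaired 3' tail: the energy is always evaluated at the full sequence
#' length, so a structure's energy never changes retroactively while the
#' transcript grows.
#'
#' @param model an [EnergyModel-class] object.
#' @param seq full-length RNA sequence (character scalar, `ACGU`).
#' @param structures character vector of dot-bracket strings; strings shorter
#'   than `seq` are padded with unpaired positions.
#' @return numeric vector of free energies in kcal/mol.
#' @export
setGeneric("freeEnergy", function(model, seq, structures)
  standardGeneric("freeEnergy"))

#' Constrained minimum-free-energy folding
#'
#' Folds the first `upTo` nucleotides of `seq` subject to a structure
#' constraint, with all positions beyond `upTo` unpaired. The returned
#' energy follows the full-length evaluation convention of [freeEnergy()].
#'
#' @param model an [EnergyModel-class] object.
#' @param seq full-length RNA sequence.
#' @param upTo transcript length; positions `> upTo` are forced unpaired.
#' @param constraint dot-bracket constraint string of length `upTo`
#'   (`'.'` free, `'x'` unpaired, `'('`/`')'` paired), or `""` for none.
#' @param enforce if `TRUE` bracketed pairs (and `'x'` loop positions) are
#'   enforced exactly; if `FALSE` they only exclude incompatible pairs.
#' @return list with elements `structure` (full-length dot-bracket),
#'   `energy` (kcal/mol) and `feasible` (logical). An infeasible constraint
#'   is reported via `feasible = FALSE`, never as a silent empty structure.
#' @export
setGeneric("constrainedMFE", function(model, seq, upTo = nchar(seq),
                                      constraint = "", enforce = FALSE)
  standardGeneric("constrainedMFE"))

#' Minimum-free-energy structure within the union of two pair sets
#'
#' Returns the lowest-energy structure whose base pairs are a subset of the
#' union of the pairs of `x` and `y`; all other pairs are forbidden. This is
#' the structure insertion step of the guide-graph construction.
#'
#' @inheritParams freeEnergy
#' @param x,y full-length dot-bracket strings.
#' @return list with `structure` and `energy`.
#' @export
setGeneric("directPathMFE", function(model, seq, x, y)
  standardGeneric("directPathMFE"))

#' Direct-path search between two structures
#'
#' Beam search (findpath-style) over all direct refolding paths from `x` to
#' `y`, i.e. paths of length `d(x, y)` whose consecutive structures differ by
#' one base pair. Among the paths explored within the beam, the one with the
#' lowest saddle energy is returned; ties are broken deterministically.
#'
#' @inheritParams directPathMFE
#' @param width beam width; by default `4 * d(x, y)`.
#' @return a [DirectPath-class] object.
#' @export
setGeneric("findDirectPath", function(model, seq, x, y, width = NULL)
  standardGeneric("findDirectPath"))

#' @rdname TrajectoryResult-class
#' @param object,x a `TrajectoryResult`.
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))

#' @rdname TrajectoryResult-class
#' @export
setGeneric("finalOccupancies", function(x) standardGeneric("finalOccupancies"))

#' @rdname TrajectoryResult-class
#' @export
setGeneric("stepStats", function(x) standardGeneric("stepStats"))

#' @rdname Landscape-class
#' @export
setGeneric("landscapeNodes", function(x) standardGeneric("landscapeNodes"))

#' @rdname Landscape-class
#' @export
setGeneric("landscapeEdges", function(x) standardGeneric("landscapeEdges"))

#' @rdname CoarseLandscape-class
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))
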