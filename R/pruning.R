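#' Select prunable representatives from a look-ahead trajectory
#'
#' A representative is prunable when its occupancy stays below the threshold
#' `o` at every time point of the look-ahead simulation; structures that
#' transiently exceed `o` (they become relevant on the timescale of
#' transcription) are exempt.
#'
#' @param lookahead occupancy matrix from [propagateOccupancies()] over the
#'   look-ahead time points (rows: times, columns: structures).
#' @param o occupancy threshold in `[0, 1)`.
#' @return character vector of prunable structures.
#' @export
selectPrunable <- function(lookahead, o) {
  if (o <= 0 || !nrow(lookahead)) return(character(0))
  peak <- apply(lookahead, 2L, max)
  colnames(lookahead)[peak < o]
}

#' Prune low-occupancy representatives
#'
#' Prunable structures are removed in ascending occupancy order (ties broken
#' by dot-bracket order) for as long as their combined occupancy remains
#' strictly below the threshold, which guarantees the surviving parents carry
#' a combined occupancy of at least `1 - o`. The removed occupancy is not
#' redistributed here: redistribution is deferred to the next expansion,
#' because structures re-discovered as candidates keep their occupancy (see
#' [resolvePrunedOccupancy()]).
#'
#' @param coarse a [CoarseLandscape-class] whose node occupancies are the
#'   current (end of extension interval) occupancies.
#' @param prunable character vector from [selectPrunable()].
#' @param o occupancy threshold.
#' @return a [PruneReport-class].
#' @export
pruneLandscape <- function(coarse, prunable, o) {
  nodes <- landscapeNodes(coarse)
  edges <- landscapeEdges(coarse)
  cand <- nodes[nodes$structure %in% prunable, , drop = FALSE]
  cand <- cand[order(cand$occupancy, cand$structure), , drop = FALSE]
  removed <- character(0)
  total <- 0
  for (r in seq_len(nrow(cand))) {
    if (total + cand$occupancy[r] < o) {
      removed <- c(removed, cand$structure[r])
      total <- total + cand$occupancy[r]
    } else break
  }
  keep <- !(nodes$structure %in% removed)
  new("PruneReport",
      parents = nodes[keep, , drop = FALSE],
      pruned = nodes[!keep, , drop = FALSE],
      graph = edges,
      threshold = o)
}

#' Resolve the deferred occupancy of pruned structures
#'
#' Called at the start of the next expansion, once the new candidate set is
#' known. A pruned structure that was re-discovered as a candidate keeps its
#' occupancy. Otherwise its occupancy is distributed evenly among the nearest
#' surviving structures in the landscape graph of the pruning step
#' (neighbors, or recursively neighbors of neighbors when all direct
#' neighbors were removed too).
#'
#' @param report a [PruneReport-class].
#' @param candidates character vector of candidate structures of the next
#'   expansion.
#' @return named numeric vector of occupancy increments (possibly empty);
#'   names are structures among `candidates`.
#' @export
resolvePrunedOccupancy <- function(report, candidates) {
  pr <- report@pruned
  if (!nrow(pr)) return(numeric(0))
  survivors <- union(report@parents$structure,
                     intersect(pr$structure, candidates))
  adj <- list()
  g <- report@graph
  for (r in seq_len(nrow(g))) {
    adj[[g$from[r]]] <- c(adj[[g$from[r]]], g$to[r])
    adj[[g$to[r]]] <- c(adj[[g$to[r]]], g$from[r])
  }
  inc <- setNames(numeric(0), character(0))
  bump <- function(s, w) {
    inc[s] <<- if (is.na(inc[s])) w else inc[s] + w
  }
  for (r in seq_len(nrow(pr))) {
    s <- pr$structure[r]
    w <- pr$occupancy[r]
    if (w == 0) next
    if (s %in% candidates) {
      bump(s, w)
      next
    }
    # breadth-first search for the nearest surviving structures
    seen <- s
    frontier <- s
    receivers <- character(0)
    while (length(frontier) && !length(receivers)) {
      nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
      if (!length(nxt)) break
      receivers <- intersect(nxt, survivors)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    if (!length(receivers)) receivers <- report@parents$structure
    receivers <- intersect(receivers, candidates)
    for (rc in receivers) bump(rc, w / length(receivers))
  }
  inc[inc != 0]
}
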