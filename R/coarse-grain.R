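#' Top-down coarse graining into delta-minimum representatives
#'
#' Processes the landscape nodes from high to low energy (ties broken by
#' dot-bracket order for reproducibility). A structure `k` is transient when
#' some reaction to an equal-or-lower-energy neighbor has saddle energy below
#' `E_k + delta` (a fast reaction); its occupancy is then divided equally
#' among the neighbors with minimal saddle energy, every neighbor reachable
#' by a fast reaction is connected with all other neighbors of `k` (two
#' neighbors that are both only reachable by slow reactions are not
#' connected), and the new edges inherit the larger of the two saddles
#' through `k`, keeping the minimum over duplicate edges. Structures that are
#' not transient are delta-minima and become representatives. Total occupancy
#' is conserved exactly.
#'
#' @param landscape a [Landscape-class] (or any object with `nodes`/`edges`
#'   data.frames as documented there).
#' @param delta barrier threshold in kcal/mol.
#' @return a [CoarseLandscape-class].
#' @export
coarseGrain <- function(landscape, delta) {
  nodes <- landscapeNodes(landscape)
  edges <- landscapeEdges(landscape)
  m <- nrow(nodes)
  stopifnot(m >= 1L, delta > 0)
  dbs <- nodes$structure
  E <- nodes$energy
  occ <- nodes$occupancy
  idx <- setNames(seq_len(m), dbs)

  S <- matrix(Inf, m, m)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- idx[[edges$from[r]]]; b <- idx[[edges$to[r]]]
      s <- edges$saddle[r]
      if (s < S[a, b]) { S[a, b] <- s; S[b, a] <- s }
    }
  }

  removed <- rep(FALSE, m)
  splits <- vector("list", m)  # immediate occupancy split of each transient
  order_ <- order(-E, dbs)
  for (k in order_) {
    nb <- which(is.finite(S[k, ]))
    if (!length(nb)) next
    fastLower <- nb[E[nb] <= E[k] & S[k, nb] < E[k] + delta]
    if (!length(fastLower)) next  # k is a delta-minimum
    removed[k] <- TRUE
    smin <- min(S[k, nb])
    targets <- nb[S[k, nb] <= smin + 1e-12]
    splits[[k]] <- data.frame(to = targets,
                              weight = 1 / length(targets))
    fast <- nb[S[k, nb] < E[k] + delta]
    for (x in fast) {
      for (y in nb) {
        if (y == x) next
        s <- max(S[k, x], S[k, y])
        if (s < S[x, y]) { S[x, y] <- s; S[y, x] <- s }
      }
    }
    S[k, ] <- Inf
    S[, k] <- Inf
  }

  # resolve transient occupancy onto representatives (follows processing
  # order, hence acyclic)
  resolved <- vector("list", m)
  resolveNode <- function(k) {
    if (!removed[k]) return(data.frame(to = k, weight = 1))
    if (!is.null(resolved[[k]])) return(resolved[[k]])
    sp <- splits[[k]]
    parts <- lapply(seq_len(nrow(sp)), function(r) {
      sub <- resolveNode(sp$to[r])
      sub$weight <- sub$weight * sp$weight[r]
      sub
    })
    out <- do.call(rbind, parts)
    out <- stats::aggregate(weight ~ to, data = out, FUN = sum)
    resolved[[k]] <<- out
    out
  }

  # resolveNode maps each transient onto representatives only, so the
  # original occupancies can be pushed through in one pass
  occOut <- occ
  basinMap <- list()
  for (k in which(removed)) {
    res <- resolveNode(k)
    occOut[res$to] <- occOut[res$to] + occ[k] * res$weight
    occOut[k] <- 0
    basinMap[[dbs[k]]] <- data.frame(structure = dbs[res$to],
                                     weight = res$weight)
  }

  keep <- which(!removed)
  repEdges <- which(is.finite(S) & upper.tri(S), arr.ind = TRUE)
  new("CoarseLandscape",
      nodes = data.frame(structure = dbs[keep], energy = E[keep],
                         occupancy = occOut[keep]),
      edges = data.frame(from = dbs[repEdges[, 1L]],
                         to = dbs[repEdges[, 2L]],
                         saddle = S[repEdges]),
      basinMap = basinMap,
      delta = delta)
}
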