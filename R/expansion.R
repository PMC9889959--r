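## ---------------------------------------------------------------------------
## Fraying constraints: candidate generation around the exterior loop
## ---------------------------------------------------------------------------

# outermost pairs (not enclosed by any other pair) of a pair table
.exteriorRoots <- function(pt) {
  n <- length(pt)
  roots <- matrix(integer(0), ncol = 2)
  i <- 1L
  while (i <= n) {
    if (pt[i] > i) {
      roots <- rbind(roots, c(i, pt[i]))
      i <- pt[i] + 1L
    } else i <- i + 1L
  }
  roots
}

# maximal stack of pairs starting at root (i, j)
.helixStack <- function(pt, i, j) {
  pairs <- matrix(integer(0), ncol = 2)
  k <- 0L
  while (i + k < j - k && pt[i + k] == j - k) {
    pairs <- rbind(pairs, c(i + k, j - k))
    k <- k + 1L
  }
  pairs
}

# pairs opened when fraying the helix rooted at (i, j): the root stack, and
# while fewer than mfree nucleotides of the span become free, the stacks of
# the next enclosed helices as well
.frayOpenSet <- function(pt, i, j, mfree) {
  opened <- .helixStack(pt, i, j)
  repeat {
    ptRem <- pt
    if (nrow(opened)) {
      ptRem[opened[, 1L]] <- 0L
      ptRem[opened[, 2L]] <- 0L
    }
    # children: outermost remaining pairs within the span
    children <- matrix(integer(0), ncol = 2)
    p <- i
    while (p <= j) {
      if (ptRem[p] > p) {
        children <- rbind(children, c(p, ptRem[p]))
        p <- ptRem[p] + 1L
      } else p <- p + 1L
    }
    liberated <- (j - i + 1L) -
      sum(children[, 2L] - children[, 1L] + 1L)
    if (liberated >= mfree || nrow(children) == 0L) break
    for (c_ in seq_len(nrow(children)))
      opened <- rbind(opened,
                      .helixStack(ptRem, children[c_, 1L], children[c_, 2L]))
  }
  opened
}

# constraint string: remaining pairs enforced, their loop regions fixed ('x'),
# everything in the exterior loop (including opened helices) free
.frayConstraint <- function(pt, opened, upTo) {
  chars <- rep(".", upTo)
  ptRem <- pt
  if (nrow(opened)) {
    ptRem[opened[, 1L]] <- 0L
    ptRem[opened[, 2L]] <- 0L
  }
  depth <- 0L
  for (p in seq_len(upTo)) {
    if (ptRem[p] > p) {
      chars[p] <- "("
      depth <- depth + 1L
    } else if (ptRem[p] != 0L && ptRem[p] < p) {
      chars[p] <- ")"
      depth <- depth - 1L
    } else if (depth > 0L) {
      chars[p] <- "x"
    }
  }
  paste(chars, collapse = "")
}

#' Fraying constraints of a parent structure
#'
#' Translates a parent conformation into folding constraints that keep all
#' base pairs and loop regions fixed except for the exterior loop and
#' combinations of the helices adjacent to it (the fraying helices): one
#' constraint per fraying helix opened separately, plus one with all fraying
#' helices opened at once. If opening a helix liberates fewer than `mfree`
#' nucleotides, the next enclosed helices are opened as well.
#'
#' @param seq RNA sequence (full length).
#' @param parent parent dot-bracket (its pairs lie within the first `upTo`
#'   positions; the newly transcribed nucleotide `upTo` is unpaired).
#' @param upTo current transcript length.
#' @param mfree minimum number of liberated nucleotides per constraint.
#' @return character vector of distinct constraint strings of length `upTo`.
#' @export
frayingConstraints <- function(seq, parent, upTo, mfree = 6L) {
  pt <- pairTable(padStructure(substr(parent, 1L, upTo), upTo))
  roots <- .exteriorRoots(pt)
  if (!nrow(roots)) return(strrep(".", upTo))
  opens <- lapply(seq_len(nrow(roots)), function(r)
    .frayOpenSet(pt, roots[r, 1L], roots[r, 2L], mfree))
  cons <- vapply(opens, function(o) .frayConstraint(pt, o, upTo), "")
  all_open <- do.call(rbind, opens)
  cons <- c(cons, .frayConstraint(pt, all_open, upTo))
  unique(cons)
}

## ---------------------------------------------------------------------------
## Candidate structures
## ---------------------------------------------------------------------------

#' Find candidate structures for the current transcript length
#'
#' The candidate set consists of the parents themselves, the results of
#' MFE folding under each parent's fraying constraints whenever the result is
#' energetically equivalent or better than its parent (tolerance
#' `tol` kcal/mol), and the unconstrained MFE structure of the current
#' transcript.
#'
#' @param model an [EnergyModel-class].
#' @param seq full-length sequence.
#' @param parents character vector of parent dot-brackets.
#' @param upTo current transcript length.
#' @param mfree see [frayingConstraints()].
#' @param tol energy tolerance for "equivalent or better" (kcal/mol).
#' @return character vector of candidate structures (full-length strings).
#' @export
findCandidates <- function(model, seq, parents, upTo, mfree = 6L,
                           tol = 0.01) {
  n <- nchar(seq)
  parents <- vapply(parents, padStructure, "", n = n, USE.NAMES = FALSE)
  cands <- parents
  if (length(parents)) {
    eP <- freeEnergy(model, seq, parents)
    folds <- new.env(parent = emptyenv())  # parents can share constraints
    for (k in seq_along(parents)) {
      for (cs in frayingConstraints(seq, parents[k], upTo, mfree)) {
        res <- get0(cs, envir = folds)
        if (is.null(res)) {
          res <- constrainedMFE(model, seq, upTo, cs, enforce = TRUE)
          assign(cs, res, envir = folds)
        }
        if (res$feasible && res$energy <= eP[k] + tol)
          cands <- c(cands, res$structure)
      }
    }
  }
  mfe <- constrainedMFE(model, seq, upTo)
  sort(unique(c(cands, mfe$structure)))
}

## ---------------------------------------------------------------------------
## Guide graph
## ---------------------------------------------------------------------------

#' Build the guiding neighborhood of a candidate set
#'
#' Iterates the three-step guide-graph construction to a fixed point:
#' (1) every node is extended by its compatible-constraint MFE structure;
#' (2) guide edges connect x and y unless some node i satisfies
#' `max(d(x,i), d(i,y)) < d(x,y)`, and shortcut edges connect guide
#' neighbors x, y of a node i when `d(x,i) + d(i,y) > d(x,y)`;
#' (3) for every edge the MFE structure within the union of the endpoint
#' pair sets is inserted as a new candidate if it differs from both
#' endpoints, in which case all edges are discarded and construction repeats.
#'
#' @inheritParams findCandidates
#' @param candidates character vector of candidate structures.
#' @param unionCache optional environment memoizing the per-edge
#'   union-constrained MFE results across calls.
#' @return list with `nodes` (character vector, sorted) and `edges`
#'   (data.frame `from`, `to`, `kind`).
#' @export
buildGuideGraph <- function(model, seq, candidates, upTo = nchar(seq),
                            unionCache = NULL) {
  n <- nchar(seq)
  nodes <- sort(unique(vapply(candidates, padStructure, "", n = n,
                              USE.NAMES = FALSE)))
  if (is.null(unionCache)) unionCache <- new.env(parent = emptyenv())
  compatDone <- character(0)
  repeat {
    # (1) compatible-constraint extension
    todo <- setdiff(nodes, compatDone)
    for (nd in todo) {
      res <- constrainedMFE(model, seq, upTo,
                            constraint = substr(nd, 1L, upTo),
                            enforce = FALSE)
      compatDone <- c(compatDone, nd)
      if (res$feasible && !res$structure %in% nodes)
        nodes <- sort(c(nodes, res$structure))
    }
    if (length(nodes) == 1L)
      return(list(nodes = nodes,
                  edges = data.frame(from = character(0), to = character(0),
                                     kind = character(0))))
    # (2) guide and shortcut edges from base-pair distances
    d <- cpp_bp_dist_matrix(nodes)
    gs <- cpp_guide_edges(d)
    sel <- which((gs$guide | gs$shortcut) & upper.tri(gs$guide),
                 arr.ind = TRUE)
    # (3) insert the union-constrained MFE of every edge
    newStructs <- character(0)
    for (r in seq_len(nrow(sel))) {
      x <- nodes[sel[r, 1L]]; y <- nodes[sel[r, 2L]]
      key <- paste(x, y)
      z <- get0(key, envir = unionCache)
      if (is.null(z)) {
        z <- directPathMFE(model, seq, x, y)$structure
        assign(key, z, envir = unionCache)
      }
      if (z != x && z != y) newStructs <- c(newStructs, z)
    }
    newStructs <- setdiff(unique(newStructs), nodes)
    if (!length(newStructs)) {
      kind <- ifelse(gs$guide[sel], "guide", "shortcut")
      return(list(nodes = nodes,
                  edges = data.frame(from = nodes[sel[, 1L]],
                                     to = nodes[sel[, 2L]],
                                     kind = kind)))
    }
    nodes <- sort(c(nodes, newStructs))
  }
}

#' Guide and shortcut edges of a fixed structure set
#'
#' The distance-based neighborhood rules alone (step two of
#' [buildGuideGraph()]), without extending the structure set: a guide edge
#' `(x, y)` exists unless some structure `i` satisfies
#' `max(d(x,i), d(i,y)) < d(x,y)`; a shortcut edge is added between guide
#' neighbors `x`, `y` of a node `i` when `d(x,i) + d(i,y) > d(x,y)`.
#'
#' @param structures character vector of dot-bracket strings (equal length).
#' @return data.frame with `from`, `to` (indices into `structures`) and
#'   `kind` (`"guide"` or `"shortcut"`).
#' @examples
#' guideEdges(c("..((...))", "..(....).", "(((...)))"))
#' @export
guideEdges <- function(structures) {
  stopifnot(length(structures) >= 2L)
  d <- cpp_bp_dist_matrix(structures)
  gs <- cpp_guide_edges(d)
  sel <- which((gs$guide | gs$shortcut) & upper.tri(gs$guide), arr.ind = TRUE)
  data.frame(from = sel[, 1L], to = sel[, 2L],
             kind = ifelse(gs$guide[sel], "guide", "shortcut"))
}

## ---------------------------------------------------------------------------
## Rates
## ---------------------------------------------------------------------------

#' Arrhenius rate from a saddle energy
#'
#' `k = k0 * exp(-(E_saddle - E_x) / RT)`. For a single base-pair move whose
#' saddle is the higher endpoint energy this reduces to the Metropolis rule
#' `k0 * min(1, exp(-dE/RT))`.
#'
#' @param energy free energy of the reactant (kcal/mol).
#' @param saddle saddle energy (kcal/mol, must not be below `energy`).
#' @param k0 pre-exponential rate constant (1/s).
#' @param temperature temperature in degrees Celsius.
#' @return rate in 1/s.
#' @examples
#' rateFromSaddle(-2, -1, k0 = 1e5)
#' @export
rateFromSaddle <- function(energy, saddle, k0, temperature = 37) {
  # slack below the 0.01 kcal/mol parameter quantum absorbs float round-off
  if (any(saddle < energy - 1e-4))
    stop("saddle energy below reactant energy")
  k0 * exp(-pmax(saddle - energy, 0) / .rt(temperature))
}

## ---------------------------------------------------------------------------
## Landscape expansion
## ---------------------------------------------------------------------------

#' Create an empty landscape for a sequence
#'
#' @param seq RNA sequence.
#' @return a [Landscape-class] with no nodes and fresh caches.
#' @export
emptyLandscape <- function(seq) {
  seq <- normalizeSequence(seq)
  cache <- new.env(parent = emptyenv())
  cache$energies <- new.env(parent = emptyenv())
  cache$reactions <- new.env(parent = emptyenv())
  cache$adjacency <- new.env(parent = emptyenv())
  cache$unionMFE <- new.env(parent = emptyenv())
  cache$ids <- new.env(parent = emptyenv())
  cache$nextId <- 1L
  new("Landscape", sequence = seq, transcriptLength = 0L,
      nodes = data.frame(structure = character(0), energy = numeric(0),
                         occupancy = numeric(0)),
      edges = data.frame(from = character(0), to = character(0),
                         saddle = numeric(0)),
      cache = cache)
}

.cachedEnergy <- function(cache, model, seq, dbs) {
  miss <- dbs[!vapply(dbs, function(s) !is.null(get0(s, cache$energies)),
                      TRUE)]
  miss <- unique(miss)
  if (length(miss)) {
    es <- freeEnergy(model, seq, miss)
    for (k in seq_along(miss)) assign(miss[k], es[k], envir = cache$energies)
  }
  vapply(dbs, function(s) get(s, envir = cache$energies), 0)
}

.structureId <- function(cache, db) {
  id <- get0(db, envir = cache$ids)
  if (is.null(id)) {
    id <- cache$nextId
    assign(db, id, envir = cache$ids)
    cache$nextId <- cache$nextId + 1L
  }
  id
}

.reactionKey <- function(x, y)
  if (x < y) paste(x, y) else paste(y, x)

.recordReaction <- function(cache, x, y, saddle) {
  key <- .reactionKey(x, y)
  old <- get0(key, envir = cache$reactions)
  if (is.null(old) || saddle < old)
    assign(key, saddle, envir = cache$reactions)
  for (p in list(c(x, y), c(y, x))) {
    adj <- get0(p[1L], envir = cache$adjacency)
    if (is.null(adj)) adj <- character(0)
    if (!p[2L] %in% adj)
      assign(p[1L], c(adj, p[2L]), envir = cache$adjacency)
  }
}

# findpath + flooding decomposition, recursing on subpaths with doubled width
.processReaction <- function(cache, model, seq, x, y, delta, widthFactor,
                             newNodes, widthMax = 32L) {
  key <- .reactionKey(x, y)
  if (!is.null(get0(key, envir = cache$reactions))) return(invisible())
  if (x > y) { tmp <- x; x <- y; y <- tmp }
  d <- basePairDistance(x, y)
  path <- findDirectPath(model, seq, x, y,
                         width = min(max(1L, ceiling(widthFactor * d)),
                                     widthMax))
  for (k in seq_along(path@steps))
    assign(path@steps[k], path@energies[k], envir = cache$energies)
  dec <- decomposeReaction(path, delta)
  if (dec$direct) {
    .recordReaction(cache, x, y, dec$saddle)
  } else {
    for (nm in dec$newMinima) assign(nm, TRUE, envir = newNodes)
    for (sp in dec$subpaths)
      .processReaction(cache, model, seq, sp[1L], sp[2L], delta,
                       widthFactor * 2, newNodes, widthMax)
  }
  invisible()
}

#' Expand the landscape for a new transcript length
#'
#' Runs one expansion phase: finds candidate structures around the parents'
#' exterior loops, builds the guiding neighborhood, determines saddle
#' energies for all new candidate reactions via direct-path search and
#' flooding (recursing on subpaths when interior delta-minima at or below the
#' endpoint energies are discovered), and merges the candidate-reaction cache
#' of previous transcript steps. With no parents the expansion yields the MFE
#' structure of the current transcript with occupancy one.
#'
#' @param landscape a [Landscape-class] (carries the persistent caches).
#' @param parents data.frame with columns `structure` and `occupancy`
#'   (occupancies of surviving representatives of the previous step), or
#'   `NULL` at the start of transcription.
#' @param newLength transcript length after the extension.
#' @param model an [EnergyModel-class].
#' @param delta barrier threshold (kcal/mol) used by path flooding.
#' @param mfree see [frayingConstraints()].
#' @param fpWidthFactor direct-path beam width as a multiple of the distance.
#' @param fpWidthMax upper bound on the beam width.
#' @param pending optional [PruneReport-class] from the previous step; pruned
#'   structures re-discovered among the candidates keep their occupancy,
#'   the rest have it redistributed (see [resolvePrunedOccupancy()]).
#' @return the expanded [Landscape-class].
#' @export
expandLandscape <- function(landscape, parents, newLength, model,
                            delta, mfree = 6L, fpWidthFactor = 4,
                            fpWidthMax = 32L, pending = NULL) {
  seq <- landscape@sequence
  cache <- landscape@cache
  if (is.null(parents) || nrow(parents) == 0L) {
    mfe <- constrainedMFE(model, seq, upTo = newLength)
    db <- mfe$structure
    assign(db, mfe$energy, envir = cache$energies)
    .structureId(cache, db)
    return(new("Landscape", sequence = seq,
               transcriptLength = as.integer(newLength),
               nodes = data.frame(structure = db, energy = mfe$energy,
                                  occupancy = 1),
               edges = data.frame(from = character(0), to = character(0),
                                  saddle = numeric(0)),
               cache = cache))
  }

  cands <- findCandidates(model, seq, parents$structure, newLength, mfree)
  gg <- buildGuideGraph(model, seq, cands, newLength,
                        unionCache = cache$unionMFE)
  nodes <- gg$nodes

  newNodes <- new.env(parent = emptyenv())
  if (nrow(gg$edges)) {
    for (r in seq_len(nrow(gg$edges)))
      .processReaction(cache, model, seq, gg$edges$from[r], gg$edges$to[r],
                       delta, fpWidthFactor, newNodes, fpWidthMax)
  }
  # all.names: dot-bracket strings routinely start with "."
  nodes <- sort(unique(c(nodes, ls(newNodes, all.names = TRUE))))

  energies <- .cachedEnergy(cache, model, seq, nodes)
  occ <- setNames(rep(0, length(nodes)), nodes)
  pocc <- setNames(parents$occupancy, parents$structure)
  occ[names(pocc)] <- occ[names(pocc)] + pocc
  if (!is.null(pending)) {
    extra <- resolvePrunedOccupancy(pending, nodes)
    if (length(extra))
      occ[names(extra)] <- occ[names(extra)] + extra
  }
  for (nd in nodes) .structureId(cache, nd)

  # edges: every cached reaction between current nodes
  ef <- character(0); et <- character(0); es <- numeric(0)
  nodeSet <- new.env(parent = emptyenv())
  for (nd in nodes) assign(nd, TRUE, envir = nodeSet)
  for (nd in nodes) {
    adj <- get0(nd, envir = cache$adjacency)
    if (is.null(adj)) next
    for (p in adj) {
      if (nd < p && !is.null(get0(p, envir = nodeSet))) {
        ef <- c(ef, nd); et <- c(et, p)
        es <- c(es, get(.reactionKey(nd, p), envir = cache$reactions))
      }
    }
  }

  new("Landscape", sequence = seq, transcriptLength = as.integer(newLength),
      nodes = data.frame(structure = nodes, energy = unname(energies),
                         occupancy = unname(occ)),
      edges = data.frame(from = ef, to = et, saddle = es),
      cache = cache)
}
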