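#' Flood a one-dimensional energy profile into delta-minima and saddles
#'
#' An interior index `k` of the profile is a delta-minimum when every escape
#' to a strictly lower-energy index crosses a barrier of at least `delta`
#' above `E_k`. Path endpoints are externally supplied structures and are
#' always reported as minima. Adjacent minima are linked by their maximal
#' intervening energy, the saddle. Because the delta-minimum test compares
#' against strictly lower energies only, the result is invariant under adding
#' a constant to all energies, and the order in which equal-energy indices
#' are considered (left to right here) does not change the minima set.
#'
#' @param energies numeric vector (length >= 2) of per-step free energies.
#' @param delta barrier threshold in kcal/mol (> 0).
#' @return a [FloodResult-class] object.
#' @examples
#' floodPath(c(0, 2, 1, 3, 0), delta = 0.5)
#' @export
floodPath <- function(energies, delta) {
  m <- length(energies)
  if (m < 2L) stop("profile must have at least two points")
  if (!is.finite(delta) || delta <= 0) stop("delta must be positive")
  isMin <- rep(FALSE, m)
  isMin[c(1L, m)] <- TRUE
  for (k in seq_len(m)[-c(1L, m)]) {
    trapped <- TRUE
    # scan left, then right, tracking the running maximum (the barrier)
    for (dir in c(-1L, 1L)) {
      bar <- -Inf
      j <- k + dir
      while (j >= 1L && j <= m) {
        bar <- max(bar, energies[j])
        if (energies[j] < energies[k] && bar - energies[k] < delta) {
          trapped <- FALSE
          break
        }
        j <- j + dir
      }
      if (!trapped) break
    }
    isMin[k] <- trapped
  }
  minima <- which(isMin)
  nsad <- length(minima) - 1L
  from <- to <- at <- integer(nsad)
  sE <- numeric(nsad)
  for (s in seq_len(nsad)) {
    a <- minima[s]; b <- minima[s + 1L]
    seg <- energies[(a + 1L):(b - 1L)]
    if (!length(seg)) {  # adjacent indices: saddle is the higher endpoint
      at[s] <- if (energies[a] >= energies[b]) a else b
      sE[s] <- max(energies[a], energies[b])
    } else {
      at[s] <- a + which.max(seg)
      sE[s] <- max(seg, energies[a], energies[b])
    }
    from[s] <- a; to[s] <- b
  }
  new("FloodResult",
      minima = minima, minimaEnergies = energies[minima],
      saddles = data.frame(from = from, to = to, at = at, energy = sE))
}

#' Decompose a direct path into a direct transition or new candidates
#'
#' A path with no interior delta-minimum at or below the higher endpoint
#' energy represents a direct transition: any intermediate basin above both
#' endpoints is short-lived, and the reaction is dominated by the maximum
#' energy along the path (the saddle). Otherwise the qualifying interior
#' delta-minima are returned as new candidate structures together with the
#' subpaths (consecutive pairs of kept structures) that must be analysed
#' in their place.
#'
#' @param path a [DirectPath-class] object.
#' @param delta barrier threshold in kcal/mol.
#' @return a list: either `list(direct = TRUE, saddle = <kcal/mol>)` or
#'   `list(direct = FALSE, newMinima = <structures>, subpaths = <list of
#'   c(from, to) structure pairs>)`.
#' @export
decomposeReaction <- function(path, delta) {
  stopifnot(is(path, "DirectPath"))
  e <- path@energies
  m <- length(e)
  if (m < 2L) return(list(direct = TRUE, saddle = e[1L]))
  fl <- floodPath(e, delta)
  interior <- setdiff(fl@minima, c(1L, m))
  emax <- max(e[1L], e[m])
  qualifying <- interior[e[interior] <= emax]
  if (!length(qualifying))
    return(list(direct = TRUE, saddle = max(e)))
  kept <- sort(unique(c(1L, qualifying, m)))
  subpaths <- lapply(seq_len(length(kept) - 1L), function(s)
    c(path@steps[kept[s]], path@steps[kept[s + 1L]]))
  list(direct = FALSE,
       newMinima = path@steps[qualifying],
       subpaths = subpaths)
}
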