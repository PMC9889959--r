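#' Simulate cotranscriptional folding of a sequence
#'
#' Runs the full transcription loop: for every transcript length the
#' landscape is expanded ([expandLandscape()]), coarse-grained into
#' delta-minimum representatives ([coarseGrain()]), occupancies are
#' propagated over the extension interval with a logarithmic look-ahead to
#' the projected end of transcription ([propagateOccupancies()]), and
#' low-occupancy representatives are pruned ([pruneLandscape()]). After the
#' last nucleotide the simulation continues to the post-transcriptional time
#' `tEnd`. The run is deterministic.
#'
#' @param seq RNA (or DNA; T is mapped to U) sequence, character scalar.
#' @param config a [SimulationConfig-class].
#' @param model an [EnergyModel-class]; defaults to the ViennaRNA backend at
#'   the configured temperature.
#' @param verbose print per-step diagnostics.
#' @return a [TrajectoryResult-class].
#' @examples
#' \donttest{
#' res <- transcribe("GGGAAAUCCCAACCUUUGGAAGGG", simConfig(tEnd = 1))
#' finalOccupancies(res)
#' }
#' @export
transcribe <- function(seq, config = simConfig(), model = NULL,
                       verbose = FALSE) {
  seq <- normalizeSequence(seq)
  L <- nchar(seq)
  validObject(config)
  if (length(config@pauseSites) &&
      any(as.integer(names(config@pauseSites)) > L))
    stop("pause site beyond sequence end")
  if (config@startLength > L) stop("startLength beyond sequence end")
  if (is.null(model))
    model <- viennaModel(config@temperature, config@noLP)
  delta <- configDelta(config)

  ls <- emptyLandscape(seq)
  parents <- NULL
  pending <- NULL
  tOffset <- 0
  rows <- list()
  stats <- list()

  for (l in seq.int(config@startLength, L)) {
    ls <- expandLandscape(ls, parents, l, model, delta,
                          mfree = config@mfree,
                          fpWidthFactor = config@fpWidthFactor,
                          fpWidthMax = config@fpWidthMax,
                          pending = pending)
    .checkConservation(sum(ls@nodes$occupancy), "expansion", l)
    cl <- coarseGrain(ls, delta)
    .checkConservation(sum(cl@nodes$occupancy), "coarse graining", l)

    grid <- lookaheadTimes(l, L, config@tExt, config@tEnd, config@pauseSites)
    tp <- gridTimes(grid)
    m <- nrow(cl@nodes)
    R <- buildRateMatrix(cl, config@k0, config@temperature)
    pInf <- equilibriumDistribution(cl@nodes$energy, config@temperature,
                                    R = R, tol = 1e-7)
    allTimes <- c(tp$linear, tp$log)
    P <- propagateOccupancies(R, cl@nodes$occupancy, allTimes, pInf = pInf)
    nlin <- length(tp$linear)

    ids <- vapply(cl@nodes$structure, function(s)
      .structureId(ls@cache, s), 0L)
    recTimes <- if (l < L) seq_len(nlin) else seq_along(allTimes)
    for (k in recTimes) .checkConservation(sum(P[k, ]), "simulation", l)
    nt <- length(recTimes)
    rows[[length(rows) + 1L]] <- data.frame(
      length = l, time_s = tOffset + rep(allTimes[recTimes], each = m),
      id = rep(unname(ids), nt),
      structure = rep(cl@nodes$structure, nt),
      energy_kcal = rep(cl@nodes$energy, nt),
      occupancy = as.vector(t(P[recTimes, , drop = FALSE])))

    nPruned <- 0L
    if (l < L) {
      occNow <- P[nlin, ]
      clNow <- new("CoarseLandscape",
                   nodes = data.frame(structure = cl@nodes$structure,
                                      energy = cl@nodes$energy,
                                      occupancy = unname(occNow)),
                   edges = cl@edges, basinMap = list(), delta = delta)
      look <- if (nrow(P) > nlin) P[seq.int(nlin + 1L, nrow(P)), , drop = FALSE]
              else P[nlin, , drop = FALSE]
      prunable <- selectPrunable(look, config@oPrune)
      report <- pruneLandscape(clNow, prunable, config@oPrune)
      if (sum(report@parents$occupancy) < 1 - config@oPrune - 1e-9)
        stop("pruning guarantee violated at length ", l)
      parents <- report@parents[, c("structure", "occupancy")]
      pending <- report
      nPruned <- nrow(report@pruned)
    }
    stats[[length(stats) + 1L]] <- data.frame(
      length = l, candidates = nrow(ls@nodes), representatives = m,
      edges = nrow(cl@edges), pruned = nPruned)
    if (verbose)
      message(sprintf("l=%d: %d candidates, %d representatives, %d edges, %d pruned",
                      l, nrow(ls@nodes), m, nrow(cl@edges), nPruned))
    tOffset <- tOffset + grid@t1
  }

  traj <- do.call(rbind, rows)
  rownames(traj) <- NULL
  new("TrajectoryResult", sequence = seq, config = config,
      trajectory = traj, stats = do.call(rbind, stats))
}

.checkConservation <- function(total, phase, l, tol = 1e-9) {
  if (abs(total - 1) > tol)
    stop(sprintf("occupancy not conserved after %s at length %d (sum = %.12f)",
                 phase, l, total))
}
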