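#' Stochastic elementary-move folding simulation (reference oracle)
#'
#' Gillespie simulation of cotranscriptional folding on the full elementary
#' move set (single base-pair opening/closing) with Metropolis rates
#' `k0 * min(1, exp(-dE/RT))`. This is the presumed ground-truth kinetic
#' model that the deterministic pipeline approximates; it is intended for
#' validation on short sequences (roughly <= 25 nt), not production use.
#' Energies are evaluated at full transcript length, matching the
#' deterministic pipeline's convention.
#'
#' @param seq RNA sequence.
#' @param config a [SimulationConfig-class]; `tExt`, `tEnd`, `k0`,
#'   `temperature`, `noLP`, `pauseSites` and `startLength` are honored.
#' @param nTraj number of trajectories.
#' @param seed integer seed.
#' @return data.frame of final structures with `count` and `frequency`,
#'   sorted by decreasing frequency.
#' @export
gillespieFold <- function(seq, config = simConfig(), nTraj = 1000L,
                          seed = 1L) {
  seq <- normalizeSequence(seq)
  L <- nchar(seq)
  sl <- config@startLength
  stepTimes <- if (sl < L) rep(config@tExt, L - sl) else numeric(0)
  if (length(config@pauseSites) && sl < L) {
    for (k in seq_along(config@pauseSites)) {
      pos <- as.integer(names(config@pauseSites)[k])
      if (pos >= sl && pos < L)
        stepTimes[pos - sl + 1L] <- stepTimes[pos - sl + 1L] +
          config@pauseSites[k]
    }
  }
  finals <- cpp_gillespie(seq, sl, stepTimes, config@tEnd, config@k0,
                          config@temperature, config@noLP,
                          as.integer(nTraj), as.integer(seed))
  tab <- sort(table(finals), decreasing = TRUE)
  data.frame(structure = names(tab), count = as.integer(tab),
             frequency = as.integer(tab) / nTraj, row.names = NULL)
}
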