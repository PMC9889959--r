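#' Generate uniform random RNA sequences
#'
#' @param n number of sequences.
#' @param length sequence length.
#' @param seed optional integer seed (local to this call).
#' @return character vector of sequences over `ACGU`.
#' @export
randomSequences <- function(n, length, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), length, replace = TRUE),
          collapse = ""), "")
}

#' How often is the most occupied structure after transcription the MFE?
#'
#' Runs the cotranscriptional simulation for `nSeqs` uniform random
#' sequences and reports the fraction whose most-occupied structure at
#' `timeAfter` seconds past the end of transcription equals the
#' thermodynamic minimum-free-energy structure of the full sequence.
#'
#' @param nSeqs number of random sequences.
#' @param length sequence length (nt).
#' @param timeAfter seconds of post-transcriptional simulation at which the
#'   ensemble is inspected.
#' @param config a [SimulationConfig-class]; its `tEnd` is replaced by
#'   `timeAfter`.
#' @param seed integer seed for the sequence sample (the simulation itself
#'   is deterministic).
#' @param model optional [EnergyModel-class].
#' @param verbose print one line per sequence.
#' @return list with `fraction` (numeric in `[0, 1]`) and `results`
#'   (data.frame: `sequence`, `top`, `mfe`, `hit`).
#' @export
mfeFractionExperiment <- function(nSeqs, length, timeAfter,
                                  config = simConfig(), seed = 1,
                                  model = NULL, verbose = FALSE) {
  stopifnot(nSeqs >= 1)
  if (is.null(model))
    model <- viennaModel(config@temperature, config@noLP)
  cfg <- config
  cfg@tEnd <- timeAfter
  seqs <- randomSequences(nSeqs, length, seed = seed)
  top <- mfe <- character(nSeqs)
  for (i in seq_len(nSeqs)) {
    res <- transcribe(seqs[i], cfg, model = model)
    fo <- finalOccupancies(res)
    top[i] <- fo$structure[1L]
    mfe[i] <- constrainedMFE(model, seqs[i])$structure
    if (verbose)
      message(sprintf("seq %d/%d: top %s MFE (%s)", i, nSeqs,
                      if (top[i] == mfe[i]) "==" else "!=", seqs[i]))
  }
  hit <- top == mfe
  list(fraction = mean(hit),
       results = data.frame(sequence = seqs, top = top, mfe = mfe,
                            hit = hit))
}
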