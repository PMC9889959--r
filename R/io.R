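#' Read a sequence from a FASTA file
#'
#' Uses the first record; extra records trigger a warning. DNA T is mapped
#' to U with a notice.
#'
#' @param path path to a FASTA file.
#' @return named character scalar (name = FASTA header).
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  if (length(set) > 1L)
    warning("FASTA file has ", length(set), " records; using the first")
  raw <- as.character(set[[1L]])
  if (grepl("[Tt]", raw))
    message("input contains T; transcribing to U")
  normalizeSequence(raw, name = names(set)[1L])
}

#' Write a folding trajectory as tab-separated text
#'
#' Columns: `length`, `time_s` (6 significant digits), `id`, `structure`,
#' `energy_kcal`, `occupancy`.
#'
#' @param x a [TrajectoryResult-class] or a trajectory data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(x, path) {
  df <- if (is(x, "TrajectoryResult")) trajectory(x) else x
  out <- df[, c("length", "time_s", "id", "structure", "energy_kcal",
                "occupancy")]
  out$time_s <- signif(out$time_s, 6)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a trajectory written by [writeTrajectory()]
#'
#' @param path file path.
#' @return data.frame with the trajectory columns.
#' @export
readTrajectory <- function(path) {
  read.delim(path, colClasses = c(length = "integer", time_s = "numeric",
                                  id = "integer", structure = "character",
                                  energy_kcal = "numeric",
                                  occupancy = "numeric"))
}
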