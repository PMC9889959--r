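#' Normalize an RNA sequence
#'
#' Uppercases, maps DNA T to U and validates the alphabet.
#'
#' @param x character scalar.
#' @param name optional sequence label, attached as the `names` attribute.
#' @return character scalar over `ACGU`.
#' @export
normalizeSequence <- function(x, name = NULL) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- chartr("t", "u", chartr("T", "U", toupper(x)))
  s <- gsub("[[:space:]]", "", s)
  if (nchar(s) < 1L) stop("sequence must have length >= 1")
  if (grepl("[^ACGU]", s))
    stop("illegal residue(s): ",
         paste(unique(strsplit(gsub("[ACGU]", "", s), "")[[1]]), collapse = ","))
  if (!is.null(name)) names(s) <- name
  s
}

#' Parse a dot-bracket string
#'
#' @param text dot-bracket string over `'.'`, `'('`, `')'`.
#' @return integer matrix with columns `i`, `j` (1-based, `i < j`) and
#'   attribute `length`; parsing alone does not check hairpin size or
#'   pairability, see [validateStructure()].
#' @examples
#' parseDotBracket("((...))")
#' @export
parseDotBracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  if (length(chars) && any(!chars %in% c(".", "(", ")")))
    stop("illegal character in dot-bracket string")
  stack <- integer(0)
  np <- 0L
  out <- matrix(NA_integer_, nrow = sum(chars == ")"), ncol = 2,
                dimnames = list(NULL, c("i", "j")))
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      np <- np + 1L
      out[np, ] <- c(stack[length(stack)], k)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  out <- out[order(out[, 1L]), , drop = FALSE]
  structure(out, length = length(chars))
}

#' Write a pair set as a dot-bracket string
#'
#' @param pairs 2-column integer matrix of pairs (i < j).
#' @param length structure length.
#' @return dot-bracket string; round-trips with [parseDotBracket()].
#' @export
dotBracket <- function(pairs, length = attr(pairs, "length")) {
  chars <- rep(".", length)
  if (NROW(pairs)) {
    chars[pairs[, 1L]] <- "("
    chars[pairs[, 2L]] <- ")"
  }
  paste(chars, collapse = "")
}

#' Pair table of a dot-bracket string
#'
#' @param db dot-bracket string.
#' @return integer vector `pt` with `pt[i]` the partner of position `i`
#'   (0 when unpaired).
#' @export
pairTable <- function(db) {
  p <- parseDotBracket(db)
  pt <- integer(attr(p, "length"))
  if (nrow(p)) {
    pt[p[, 1L]] <- p[, 2L]
    pt[p[, 2L]] <- p[, 1L]
  }
  pt
}

.CANONICAL <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Validate a secondary structure against a sequence
#'
#' Checks the four structure conditions: (i) pairable (isosteric) base pairs
#' only, (ii) each position in at most one pair, (iii) no crossing
#' (pseudoknotted) pairs, (iv) hairpin loops of at least three unpaired
#' nucleotides (`j - i > 3`).
#'
#' @param seq RNA sequence (character scalar).
#' @param x dot-bracket string or 2-column pair matrix.
#' @return character vector of violations; empty when the structure is valid.
#' @examples
#' validateStructure("GGGAAACCC", "(((...)))")
#' @export
validateStructure <- function(seq, x) {
  seq <- normalizeSequence(seq)
  p <- if (is.character(x)) parseDotBracket(x) else x
  n <- nchar(seq)
  res <- character(0)
  if (!NROW(p)) return(res)
  bases <- strsplit(seq, "")[[1]]
  for (k in seq_len(nrow(p))) {
    i <- p[k, 1L]; j <- p[k, 2L]
    if (j > n) {
      res <- c(res, sprintf("pair (%d,%d) outside sequence", i, j))
      next
    }
    bp <- paste0(bases[i], bases[j])
    if (!bp %in% .CANONICAL)
      res <- c(res, sprintf("condition i: %s at (%d,%d) not isosteric", bp, i, j))
    if (j - i <= 3)
      res <- c(res, sprintf("condition iv: hairpin of pair (%d,%d) too small", i, j))
  }
  idx <- as.vector(p)
  dup <- unique(idx[duplicated(idx)])
  for (d in dup)
    res <- c(res, sprintf("condition ii: index %d pairs more than once", d))
  if (nrow(p) > 1L) {
    for (a in seq_len(nrow(p) - 1L)) {
      for (b in (a + 1L):nrow(p)) {
        i <- p[a, 1L]; j <- p[a, 2L]; q1 <- p[b, 1L]; q2 <- p[b, 2L]
        if (i < q1 && q1 < j && j < q2)
          res <- c(res, sprintf("condition iii: pairs (%d,%d) and (%d,%d) cross",
                                i, j, q1, q2))
      }
    }
  }
  res
}

#' Base-pair distance between two structures
#'
#' The cardinality of the symmetric difference of the two pair sets; a metric
#' on structures of the same length.
#'
#' @param x,y dot-bracket strings of equal length.
#' @return non-negative integer.
#' @examples
#' basePairDistance("((...))", ".(...).")
#' @export
basePairDistance <- function(x, y) {
  if (nchar(x) != nchar(y)) stop("structures must have equal length")
  as.integer(cpp_bp_dist_matrix(c(x, y))[1L, 2L])
}

#' All valid structures one elementary move away
#'
#' Enumerates every structure at base-pair distance exactly one from `x`:
#' each pair of `x` opened, and every insertable pair (pairable bases,
#' `j - i > 3`, both positions unpaired, non-crossing) closed.
#'
#' @param seq RNA sequence.
#' @param x dot-bracket string (must be valid for `seq`).
#' @return character vector of dot-bracket strings.
#' @export
elementaryNeighbors <- function(seq, x) {
  seq <- normalizeSequence(seq)
  n <- nchar(seq)
  if (nchar(x) != n) stop("structure length must match sequence length")
  pt <- pairTable(x)
  bases <- strsplit(seq, "")[[1]]
  chars <- strsplit(x, "")[[1]]
  out <- character(0)
  for (i in seq_len(n)) {
    if (pt[i] > i) {  # opening
      ch <- chars; ch[i] <- "."; ch[pt[i]] <- "."
      out <- c(out, paste(ch, collapse = ""))
    }
  }
  for (i in seq_len(n)) {
    if (pt[i] != 0L) next
    if (i + 4L > n) next
    for (j in (i + 4L):n) {
      if (pt[j] != 0L) next
      if (!paste0(bases[i], bases[j]) %in% .CANONICAL) next
      inner <- pt[(i + 1L):(j - 1L)]
      if (any(inner != 0L & (inner < i | inner > j))) next
      ch <- chars; ch[i] <- "("; ch[j] <- ")"
      out <- c(out, paste(ch, collapse = ""))
    }
  }
  unique(out)
}
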