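# pad a dot-bracket string with unpaired positions up to length n
padStructure <- function(db, n) {
  k <- nchar(db)
  if (k > n) stop("structure longer than sequence")
  if (k == n) db else paste0(db, strrep(".", n - k))
}

## ---------------------------------------------------------------------------
## ViennaRNA backend
## ---------------------------------------------------------------------------

setMethod("freeEnergy", "ViennaEnergyModel", function(model, seq, structures) {
  seq <- normalizeSequence(seq)
  n <- nchar(seq)
  padded <- vapply(structures, padStructure, "", n = n, USE.NAMES = FALSE)
  cpp_eval_structures(seq, padded, model@temperature, model@noLP)
})

setMethod("constrainedMFE", "ViennaEnergyModel",
          function(model, seq, upTo = nchar(seq), constraint = "",
                   enforce = FALSE) {
  seq <- normalizeSequence(seq)
  n <- nchar(seq)
  stopifnot(upTo >= 1, upTo <= n)
  if (nzchar(constraint) && nchar(constraint) != upTo)
    stop("constraint must have length upTo")
  prefix <- substr(seq, 1L, upTo)
  res <- cpp_mfe(prefix, constraint, enforce, model@temperature, model@noLP)
  if (res$feasible && enforce && nzchar(constraint)) {
    # the engine drops unsatisfiable enforced pairs rather than failing;
    # verify the constraint is actually met
    pt <- pairTable(padStructure(res$structure, upTo))
    cp <- parseDotBracket(gsub("[x<>]", ".", constraint))
    xpos <- which(strsplit(constraint, "")[[1]] == "x")
    ok <- (!nrow(cp) || all(pt[cp[, 1L]] == cp[, 2L])) &&
      (!length(xpos) || all(pt[xpos] == 0L))
    if (!ok) res$feasible <- FALSE
  }
  if (!res$feasible)
    return(list(structure = NA_character_, energy = NA_real_,
                feasible = FALSE))
  db <- padStructure(res$structure, n)
  list(structure = db,
       energy = freeEnergy(model, seq, db),
       feasible = TRUE)
})

setMethod("directPathMFE", "ViennaEnergyModel", function(model, seq, x, y) {
  seq <- normalizeSequence(seq)
  n <- nchar(seq)
  x <- padStructure(x, n); y <- padStructure(y, n)
  pairs <- unique(rbind(parseDotBracket(x), parseDotBracket(y)))
  # fold at full length: every admissible structure only uses union pairs,
  # and full-length folding keeps the energies on the package's evaluation
  # convention (unpaired 3' tail contributes its dangles)
  res <- cpp_mfe_union(seq, pairs, model@temperature, model@noLP)
  if (!res$feasible) stop("union-constrained fold failed")  # cannot happen: x, y feasible
  db <- padStructure(res$structure, n)
  list(structure = db, energy = freeEnergy(model, seq, db))
})

setMethod("findDirectPath", "ViennaEnergyModel",
          function(model, seq, x, y, width = NULL) {
  seq <- normalizeSequence(seq)
  n <- nchar(seq)
  x <- padStructure(x, n); y <- padStructure(y, n)
  d <- basePairDistance(x, y)
  if (d == 0L)
    return(new("DirectPath", steps = x,
               energies = freeEnergy(model, seq, x), width = 1L))
  if (is.null(width)) width <- 4L * d
  res <- cpp_findpath(seq, x, y, as.integer(width),
                      model@temperature, model@noLP)
  new("DirectPath", steps = res$steps, energies = res$energies,
      width = as.integer(res$width))
})

## ---------------------------------------------------------------------------
## Toy backend: additive pair/stack energies, exhaustive folding
## ---------------------------------------------------------------------------

setMethod("freeEnergy", "ToyEnergyModel", function(model, seq, structures) {
  seq <- normalizeSequence(seq)
  n <- nchar(seq)
  bases <- strsplit(seq, "")[[1]]
  vapply(structures, function(db) {
    db <- padStructure(db, n)
    p <- parseDotBracket(db)
    if (!nrow(p)) return(0)
    pt <- integer(n)
    pt[p[, 1L]] <- p[, 2L]; pt[p[, 2L]] <- p[, 1L]
    e <- sum(model@pairEnergies[paste0(bases[p[, 1L]], bases[p[, 2L]])])
    for (k in seq_len(nrow(p))) {
      i <- p[k, 1L]; j <- p[k, 2L]
      if (i + 1L <= n && pt[i + 1L] == j - 1L && j - 1L > i + 1L)
        e <- e + model@stackBonus
    }
    unname(e)
  }, 0, USE.NAMES = FALSE)
})

# all pairable (i, j) with j - i > 3 on the first `upTo` nucleotides
.allowedPairs <- function(seq, upTo = nchar(seq)) {
  bases <- strsplit(seq, "")[[1]]
  out <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  for (i in seq_len(max(upTo - 4L, 0L))) {
    for (j in (i + 4L):upTo) {
      if (paste0(bases[i], bases[j]) %in% .CANONICAL)
        out <- rbind(out, c(i, j))
    }
  }
  out
}

.pairsCompatible <- function(i, j, p, q) {
  if (i == p || i == q || j == p || j == q) return(FALSE)
  if (i < p && p < j && j < q) return(FALSE)
  if (p < i && i < q && q < j) return(FALSE)
  TRUE
}

# all non-crossing subsets of `cand` that contain all of `required`
.enumeratePairSubsets <- function(cand, required = NULL) {
  m <- nrow(cand)
  sets <- list(matrix(integer(0), ncol = 2))
  for (k in seq_len(m)) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    added <- lapply(sets, function(s) {
      if (nrow(s)) {
        for (r in seq_len(nrow(s)))
          if (!.pairsCompatible(i, j, s[r, 1L], s[r, 2L])) return(NULL)
      }
      rbind(s, c(i, j))
    })
    sets <- c(sets, added[!vapply(added, is.null, TRUE)])
  }
  if (!is.null(required) && nrow(required)) {
    keep <- vapply(sets, function(s) {
      if (nrow(s) < nrow(required)) return(FALSE)
      all(apply(required, 1L, function(r)
        any(s[, 1L] == r[1L] & s[, 2L] == r[2L])))
    }, TRUE)
    sets <- sets[keep]
  }
  sets
}

# exhaustive constrained fold used by the toy backend
.toyConstrainedFold <- function(model, seq, upTo, constraint, enforce) {
  n <- nchar(seq)
  cand <- .allowedPairs(seq, upTo)
  required <- NULL
  if (nzchar(constraint)) {
    cpairs <- parseDotBracket(gsub("[x<>]", ".", constraint))
    xpos <- which(strsplit(constraint, "")[[1]] == "x")
    if (enforce) {
      required <- cpairs
      # enforce loop regions: 'x' positions stay unpaired
      if (length(xpos))
        cand <- cand[!(cand[, 1L] %in% xpos | cand[, 2L] %in% xpos), ,
                     drop = FALSE]
      # forbid pairs incompatible with required pairs
      if (nrow(required) && nrow(cand)) {
        ok <- apply(cand, 1L, function(p) {
          inreq <- any(required[, 1L] == p[1L] & required[, 2L] == p[2L])
          if (inreq) return(TRUE)
          all(apply(required, 1L, function(r)
            .pairsCompatible(p[1L], p[2L], r[1L], r[2L])))
        })
        cand <- cand[ok, , drop = FALSE]
      }
    } else {
      # compatible mode: only exclude pairs incompatible with constraint pairs
      if (length(xpos))
        cand <- cand[!(cand[, 1L] %in% xpos | cand[, 2L] %in% xpos), ,
                     drop = FALSE]
      if (nrow(cpairs) && nrow(cand)) {
        ok <- apply(cand, 1L, function(p) {
          inc <- any(cpairs[, 1L] == p[1L] & cpairs[, 2L] == p[2L])
          if (inc) return(TRUE)
          all(apply(cpairs, 1L, function(r)
            .pairsCompatible(p[1L], p[2L], r[1L], r[2L])))
        })
        cand <- cand[ok, , drop = FALSE]
      }
    }
  }
  sets <- .enumeratePairSubsets(cand, required)
  if (!length(sets))
    return(list(structure = NA_character_, energy = NA_real_,
                feasible = FALSE))
  dbs <- vapply(sets, function(s) padStructure(dotBracket(s, upTo), n), "")
  es <- freeEnergy(model, seq, dbs)
  best <- order(es, dbs)[1L]
  list(structure = dbs[best], energy = es[best], feasible = TRUE)
}

setMethod("constrainedMFE", "ToyEnergyModel",
          function(model, seq, upTo = nchar(seq), constraint = "",
                   enforce = FALSE) {
  seq <- normalizeSequence(seq)
  stopifnot(upTo >= 1, upTo <= nchar(seq))
  if (nzchar(constraint) && nchar(constraint) != upTo)
    stop("constraint must have length upTo")
  .toyConstrainedFold(model, seq, upTo, constraint, enforce)
})

setMethod("directPathMFE", "ToyEnergyModel", function(model, seq, x, y) {
  seq <- normalizeSequence(seq)
  n <- nchar(seq)
  x <- padStructure(x, n); y <- padStructure(y, n)
  cand <- unique(rbind(parseDotBracket(x), parseDotBracket(y)))
  sets <- .enumeratePairSubsets(cand)
  dbs <- vapply(sets, function(s) dotBracket(s, n), "")
  es <- freeEnergy(model, seq, dbs)
  best <- order(es, dbs)[1L]
  list(structure = dbs[best], energy = es[best])
})

# beam search over direct paths with energies from an arbitrary model
.beamDirectPath <- function(model, seq, x, y, width) {
  ptx <- pairTable(x); pty <- pairTable(y)
  n <- length(ptx)
  opens <- which(ptx > seq_len(n) & pty != ptx)
  closes <- which(pty > seq_len(n) & ptx != pty)
  moves <- rbind(
    if (length(opens)) cbind(opens, ptx[opens], 0L),
    if (length(closes)) cbind(closes, pty[closes], 1L))
  moves <- moves[order(moves[, 1L], moves[, 2L], moves[, 3L]), , drop = FALSE]
  d <- nrow(moves)
  e0 <- freeEnergy(model, seq, x)
  beam <- list(list(pt = ptx, e = e0, saddle = e0, applied = integer(0)))
  for (level in seq_len(d)) {
    children <- list()
    for (s in beam) {
      left <- setdiff(seq_len(d), s$applied)
      for (m in left) {
        i <- moves[m, 1L]; j <- moves[m, 2L]; close <- moves[m, 3L] == 1L
        pt <- s$pt
        if (close) {
          if (pt[i] != 0L || pt[j] != 0L) next
          inner <- pt[(i + 1L):(j - 1L)]
          if (any(inner != 0L & (inner < i | inner > j))) next
          pt[i] <- j; pt[j] <- i
        } else {
          if (pt[i] != j) next
          pt[i] <- 0L; pt[j] <- 0L
        }
        db <- dotBracket(cbind(which(pt > seq_len(n)),
                               pt[pt > seq_len(n)]), n)
        e <- freeEnergy(model, seq, db)
        children[[length(children) + 1L]] <-
          list(pt = pt, e = e, saddle = max(s$saddle, e),
               applied = c(s$applied, m), db = db)
      }
    }
    key <- vapply(children, function(c) c$db, "")
    sad <- vapply(children, function(c) c$saddle, 0)
    en <- vapply(children, function(c) c$e, 0)
    ord <- order(sad, en, key)
    children <- children[ord]; key <- key[ord]
    beam <- children[!duplicated(key)]
    if (length(beam) > width) beam <- beam[seq_len(width)]
  }
  best <- beam[[1L]]
  # replay to emit the path
  pt <- ptx
  steps <- character(d + 1L); steps[1L] <- x
  for (k in seq_len(d)) {
    m <- best$applied[k]
    i <- moves[m, 1L]; j <- moves[m, 2L]
    if (moves[m, 3L] == 1L) { pt[i] <- j; pt[j] <- i }
    else { pt[i] <- 0L; pt[j] <- 0L }
    steps[k + 1L] <- dotBracket(cbind(which(pt > seq_len(n)),
                                      pt[pt > seq_len(n)]), n)
  }
  new("DirectPath", steps = steps,
      energies = freeEnergy(model, seq, steps), width = as.integer(width))
}

setMethod("findDirectPath", "ToyEnergyModel",
          function(model, seq, x, y, width = NULL) {
  seq <- normalizeSequence(seq)
  n <- nchar(seq)
  x <- padStructure(x, n); y <- padStructure(y, n)
  d <- basePairDistance(x, y)
  if (d == 0L)
    return(new("DirectPath", steps = x,
               energies = freeEnergy(model, seq, x), width = 1L))
  if (is.null(width)) width <- 4L * d
  .beamDirectPath(model, seq, x, y, as.integer(width))
})
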