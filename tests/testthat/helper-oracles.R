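# shared fixtures and independent brute-force oracles

toy <- toyModel()

# full structure ensemble of a short sequence: breadth-first search over
# elementary moves starting from the open chain
enumerateEnsemble <- function(seq) {
  n <- nchar(seq)
  seen <- new.env(parent = emptyenv())
  frontier <- strrep(".", n)
  assign(frontier, TRUE, envir = seen)
  while (length(frontier)) {
    nxt <- character(0)
    for (x in frontier) {
      for (y in elementaryNeighbors(seq, x)) {
        if (is.null(get0(y, envir = seen))) {
          assign(y, TRUE, envir = seen)
          nxt <- c(nxt, y)
        }
      }
    }
    frontier <- nxt
  }
  sort(ls(seen, all.names = TRUE))
}

# delta-minimum definition on a 1-D profile by explicit enumeration of all sub-intervals
bruteProfileMinima <- function(e, delta) {
  m <- length(e)
  mins <- c(1L, m)
  for (k in seq_len(m)[-c(1L, m)]) {
    trapped <- TRUE
    for (j in seq_len(m)) {
      if (e[j] >= e[k]) next
      saddle <- max(e[min(j, k):max(j, k)])
      if (saddle - e[k] < delta) { trapped <- FALSE; break }
    }
    if (trapped) mins <- c(mins, k)
  }
  sort(unique(mins))
}

# delta-minimum definition on a landscape graph: minimax path saddles by Floyd-Warshall
bruteGraphDeltaMinima <- function(nodes, edges, delta) {
  m <- nrow(nodes)
  idx <- setNames(seq_len(m), nodes$structure)
  S <- matrix(Inf, m, m)
  diag(S) <- -Inf
  for (r in seq_len(nrow(edges))) {
    a <- idx[[edges$from[r]]]; b <- idx[[edges$to[r]]]
    S[a, b] <- S[b, a] <- min(S[a, b], edges$saddle[r])
  }
  for (k in seq_len(m)) {
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        v <- max(S[i, k], S[k, j])
        if (v < S[i, j]) S[i, j] <- v
      }
    }
  }
  E <- nodes$energy
  keep <- vapply(seq_len(m), function(k) {
    lower <- which(E < E[k])
    !any(S[k, lower] - E[k] < delta)
  }, TRUE)
  nodes$structure[keep]
}

# random connected landscape with consistent saddles; structures are just
# distinct labels
# continuous energies avoid exact ties, where the package's transient test
# (non-strict <=) deliberately differs from the strict delta-minimum definition
randomLandscape <- function(m, extraEdges = m, zeroBarrier = FALSE) {
  labs <- sprintf("s%02d", seq_len(m))
  E <- stats::runif(m, -5, 5)
  occ <- stats::runif(m); occ <- occ / sum(occ)
  from <- to <- character(0)
  for (k in 2:m) {  # random spanning tree keeps the graph connected
    j <- sample(k - 1L, 1L)
    from <- c(from, labs[j]); to <- c(to, labs[k])
  }
  for (r in seq_len(extraEdges)) {
    ab <- sample(m, 2L)
    from <- c(from, labs[ab[1L]]); to <- c(to, labs[ab[2L]])
  }
  keep <- !duplicated(paste(pmin(from, to), pmax(from, to)))
  from <- from[keep]; to <- to[keep]
  en <- setNames(E, labs)
  saddle <- pmax(en[from], en[to]) +
    if (zeroBarrier) 0 else stats::rexp(length(from), 1)
  list(nodes = data.frame(structure = labs, energy = E, occupancy = occ),
       edges = data.frame(from = from, to = to, saddle = unname(saddle)))
}

# wrap a plain nodes/edges list into a Landscape object
asLandscape <- function(lst) {
  cache <- new.env(parent = emptyenv())
  new("Landscape", sequence = "A", transcriptLength = 1L,
      nodes = lst$nodes, edges = lst$edges, cache = cache)
}

# exhaustive minimal saddle over all direct paths (all move orders), d <= 6
bruteDirectSaddle <- function(model, seq, x, y) {
  n <- nchar(seq)
  ptx <- pairTable(x); pty <- pairTable(y)
  opens <- which(ptx > seq_len(n) & pty != ptx)
  closes <- which(pty > seq_len(n) & ptx != pty)
  moves <- rbind(
    if (length(opens)) cbind(opens, ptx[opens], 0L),
    if (length(closes)) cbind(closes, pty[closes], 1L))
  d <- nrow(moves)
  stopifnot(d <= 6L)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (ord in perms(seq_len(d))) {
    pt <- ptx
    ok <- TRUE
    sad <- freeEnergy(model, seq, x)
    for (mi in ord) {
      i <- moves[mi, 1L]; j <- moves[mi, 2L]
      if (moves[mi, 3L] == 1L) {
        if (pt[i] != 0L || pt[j] != 0L) { ok <- FALSE; break }
        inner <- pt[(i + 1L):(j - 1L)]
        if (any(inner != 0L & (inner < i | inner > j))) { ok <- FALSE; break }
        pt[i] <- j; pt[j] <- i
      } else {
        if (pt[i] != j) { ok <- FALSE; break }
        pt[i] <- 0L; pt[j] <- 0L
      }
      db <- dotBracket(cbind(which(pt > seq_len(n)), pt[pt > seq_len(n)]), n)
      sad <- max(sad, freeEnergy(model, seq, db))
    }
    if (ok) best <- min(best, sad)
  }
  best
}

# steepest-descent local minimum of a structure (deterministic tie-break)
descendToMinimum <- function(model, seq, db) {
  repeat {
    nb <- elementaryNeighbors(seq, db)
    es <- freeEnergy(model, seq, nb)
    e0 <- freeEnergy(model, seq, db)
    k <- which(es < e0 - 1e-9)
    if (!length(k)) return(db)
    db <- nb[k[order(es[k], nb[k])]][1L]
  }
}

# Gillespie simulation of a coarse Markov chain (column-generator R)
gillespieChain <- function(R, p0, tmax, ntraj) {
  m <- nrow(R)
  counts <- numeric(m)
  for (tr in seq_len(ntraj)) {
    s <- sample.int(m, 1L, prob = p0)
    t <- 0
    repeat {
      rates <- R[, s]; rates[s] <- 0
      q <- sum(rates)
      if (q <= 0) break
      t <- t + stats::rexp(1L, q)
      if (t > tmax) break
      s <- sample.int(m, 1L, prob = rates)
    }
    counts[s] <- counts[s] + 1
  }
  counts / ntraj
}
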