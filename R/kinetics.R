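#' Build the master-equation rate matrix of a coarse landscape
#'
#' Column-generator convention: `R[j, i] = k(i -> j)` for `i != j` and
#' `R[i, i] = -sum_j k(i -> j)`, so every column sums to zero and
#' `dp/dt = R p`. Rates follow the Arrhenius model from the minimal observed
#' saddle energies (see [rateFromSaddle()]), which makes the system obey
#' detailed balance by construction.
#'
#' @param coarse a [CoarseLandscape-class] (or a [Landscape-class]).
#' @param k0 pre-exponential rate constant (1/s).
#' @param temperature degrees Celsius.
#' @return square numeric matrix with structures as dimnames.
#' @export
buildRateMatrix <- function(coarse, k0, temperature = 37) {
  nodes <- landscapeNodes(coarse)
  edges <- landscapeEdges(coarse)
  m <- nrow(nodes)
  R <- matrix(0, m, m, dimnames = list(nodes$structure, nodes$structure))
  if (nrow(edges)) {
    idx <- setNames(seq_len(m), nodes$structure)
    for (r in seq_len(nrow(edges))) {
      a <- idx[[edges$from[r]]]; b <- idx[[edges$to[r]]]
      s <- edges$saddle[r]
      R[b, a] <- R[b, a] + rateFromSaddle(nodes$energy[a], s, k0, temperature)
      R[a, b] <- R[a, b] + rateFromSaddle(nodes$energy[b], s, k0, temperature)
    }
  }
  diag(R) <- 0
  diag(R) <- -colSums(R)
  R
}

#' Equilibrium (Boltzmann) distribution over representatives
#'
#' By detailed balance the stationary distribution of the rate matrix is the
#' Boltzmann distribution restricted to the representatives:
#' `p_inf propto exp(-E/RT)`.
#'
#' @param energies numeric vector of free energies (kcal/mol).
#' @param temperature degrees Celsius.
#' @param R optional rate matrix; when supplied, the stationarity residual
#'   `max |R p_inf|` is checked against `tol` and a violation raises an
#'   error (it signals an upstream detailed-balance bug).
#' @param tol residual tolerance.
#' @return numeric probability vector.
#' @export
equilibriumDistribution <- function(energies, temperature = 37, R = NULL,
                                    tol = 1e-9) {
  w <- exp(-(energies - min(energies)) / .rt(temperature))
  p <- w / sum(w)
  if (!is.null(R)) {
    resid <- max(abs(R %*% p)) / max(1, max(abs(R)))
    if (resid > tol)
      stop("rate matrix is not stationary under the Boltzmann distribution ",
           "(detailed-balance violation; residual ", format(resid), ")")
  }
  p
}

# stationary vector inferred from the rates themselves (spanning-tree walk);
# errors if the rates do not satisfy detailed balance
.stationaryFromRates <- function(R, tol = 1e-6) {
  m <- nrow(R)
  logp <- rep(NA_real_, m)
  logp[1L] <- 0
  queue <- 1L
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    for (j in seq_len(m)) {
      if (j == i || !is.na(logp[j])) next
      kij <- R[j, i]  # i -> j
      kji <- R[i, j]
      if (kij > 0 && kji > 0) {
        logp[j] <- logp[i] + log(kij) - log(kji)
        queue <- c(queue, j)
      }
    }
  }
  if (anyNA(logp)) stop("rate graph is not connected")
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  # detailed-balance check over all edges
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i < j && (R[j, i] > 0 || R[i, j] > 0)) {
      f <- p[i] * R[j, i]; b <- p[j] * R[i, j]
      if (abs(f - b) > tol * max(f, b, 1e-300))
        stop("detailed balance violated for a state pair")
    }
  }
  p
}

#' Propagate occupancies under the master equation
#'
#' Solves `p_t = exp(R t) p0`. The primary path symmetrizes the generator
#' with the square root of the stationary distribution,
#' `U = D^-1 R D` with `D = diag(sqrt(p_inf))` (symmetric under detailed
#' balance), eigendecomposes `U` once, and evaluates all requested times from
#' the decomposition. On numerical failure, or with `method = "pade"`, each
#' time point is computed with a Padé matrix exponential instead. Outputs are
#' clipped to non-negative values and renormalized.
#'
#' @param R rate matrix (column generator, see [buildRateMatrix()]).
#' @param p0 initial occupancy vector (sums to one).
#' @param times numeric vector of time points (seconds, >= 0).
#' @param pInf optional stationary distribution; inferred from `R` when
#'   missing.
#' @param method `"eigen"` (default, with Padé fallback) or `"pade"`.
#' @return matrix with one row per time point, columns as in `R`.
#' @export
propagateOccupancies <- function(R, p0, times, pInf = NULL,
                                 method = c("eigen", "pade")) {
  method <- match.arg(method)
  m <- nrow(R)
  stopifnot(length(p0) == m, all(is.finite(p0)), all(times >= 0))
  if (abs(sum(p0) - 1) > 1e-6) stop("p0 must sum to one")
  if (m == 1L)
    return(matrix(1, length(times), 1L, dimnames = list(NULL, colnames(R))))

  out <- NULL
  if (method == "eigen") {
    out <- tryCatch({
      if (is.null(pInf)) pInf <- .stationaryFromRates(R)
      d <- sqrt(pmax(pInf, 1e-300))
      U <- R * rep(d, each = m) / rep(d, times = m)  # D^-1 R D
      asym <- max(abs(U - t(U)))
      if (asym > 1e-6 * max(1, max(abs(U))))
        stop("symmetrized generator is not symmetric")
      U <- (U + t(U)) / 2
      eg <- eigen(U, symmetric = TRUE)
      lam <- pmin(eg$values, 0)  # generator spectrum is non-positive
      coef <- crossprod(eg$vectors, p0 / d)
      P <- t(vapply(times, function(tt)
        d * as.vector(eg$vectors %*% (exp(lam * tt) * coef)),
        numeric(m)))
      # badly conditioned symmetrizations (huge equilibrium spreads) show up
      # as visible negative mass; defer to the Padé route then
      if (any(P < -1e-7) || any(abs(rowSums(P) - 1) > 1e-6))
        stop("eigendecomposition route lost accuracy")
      P
    }, error = function(e) NULL)
  }
  if (is.null(out)) {
    P <- matrix(0, length(times), m)
    for (k in seq_along(times)) {
      Et <- as.matrix(Matrix::expm(R * times[k]))
      P[k, ] <- as.vector(Et %*% p0)
    }
    out <- P
  }
  out[out < 0 & out > -1e-5] <- 0
  out[abs(out) < 1e-16] <- 0
  if (any(out < 0)) stop("propagation produced negative occupancies")
  out <- out / rowSums(out)
  colnames(out) <- colnames(R)
  out
}

#' Simulation time grid for a transcription step
#'
#' During transcription the logarithmic look-ahead regime extends to the
#' projected end of transcription, `t8 = sum of the extension times of all
#' nucleotides still to come` (including pause-site extensions); after the
#' last nucleotide it extends to the post-transcriptional simulation time.
#'
#' @param l current transcript length.
#' @param L full sequence length.
#' @param tExt extension time per nucleotide (seconds).
#' @param tEnd post-transcriptional simulation time (seconds).
#' @param pauseSites named numeric vector of extra seconds per position.
#' @return a [TimeGrid-class] with `t1` the current extension interval and
#'   `t8` the look-ahead horizon.
#' @export
lookaheadTimes <- function(l, L, tExt, tEnd, pauseSites = numeric(0)) {
  stopifnot(l >= 1, l <= L)
  pause <- function(k) {
    if (!length(pauseSites)) return(0)
    p <- unname(pauseSites[as.character(k)])
    if (is.na(p)) 0 else p
  }
  if (l == L) {
    t1 <- min(tExt, tEnd)
    t8 <- tEnd
  } else {
    t1 <- tExt + pause(l)
    ks <- (l + 1):L
    t8 <- sum(tExt + vapply(ks, pause, 0))
  }
  new("TimeGrid", t0 = 0, t1 = t1, t8 = max(t8, t1))
}

#' Concrete time points of a grid
#'
#' @param grid a [TimeGrid-class].
#' @return list with `linear` (points in `[t0, t1]`, including `t1`) and
#'   `log` (geometrically spaced points in `(t1, t8]`, empty when
#'   `t8 == t1`).
#' @export
gridTimes <- function(grid) {
  lin <- seq(grid@t0, grid@t1, length.out = grid@linearPoints + 1L)[-1L]
  if (grid@t8 > grid@t1) {
    ndec <- log10(grid@t8 / grid@t1)
    npts <- max(2L, ceiling(ndec * grid@logPerDecade))
    lg <- grid@t1 * 10^(seq(0, ndec, length.out = npts + 1L)[-1L])
    lg[length(lg)] <- grid@t8
  } else {
    lg <- numeric(0)
  }
  list(linear = lin, log = lg)
}
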