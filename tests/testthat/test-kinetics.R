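mkCoarse <- function(nodes, edges, delta = 1)
  new("CoarseLandscape", nodes = nodes, edges = edges, basinMap = list(),
      delta = delta)

test_that("the rate matrix is a column generator", {
  # single state
  cl <- mkCoarse(data.frame(structure = "a", energy = 0, occupancy = 1),
                 data.frame(from = character(0), to = character(0),
                            saddle = numeric(0)))
  R <- buildRateMatrix(cl, k0 = 1e5)
  expect_equal(unname(R), matrix(0, 1, 1))

  # two states, equal energies, shared saddle: symmetric rates
  cl2 <- mkCoarse(data.frame(structure = c("a", "b"), energy = c(-1, -1),
                             occupancy = c(1, 0)),
                  data.frame(from = "a", to = "b", saddle = 0))
  R2 <- buildRateMatrix(cl2, k0 = 1e5)
  k <- 1e5 * exp(-1 / (0.00198717 * 310.15))
  expect_equal(unname(R2), matrix(c(-k, k, k, -k), 2), tolerance = 1e-9)

  # three-state chain: columns sum to zero, off-diagonals non-negative
  cl3 <- mkCoarse(data.frame(structure = c("a", "b", "c"),
                             energy = c(-2, -1, -3), occupancy = c(1, 0, 0)),
                  data.frame(from = c("a", "b"), to = c("b", "c"),
                             saddle = c(0.5, 1)))
  R3 <- buildRateMatrix(cl3, k0 = 1e5)
  expect_equal(unname(colSums(R3)), rep(0, 3), tolerance = 1e-12)
  off <- R3; diag(off) <- 0
  expect_true(all(off >= 0))
  expect_true(all(diag(R3) <= 0))
})

test_that("the equilibrium distribution is Boltzmann and stationary", {
  expect_equal(equilibriumDistribution(c(-1, -1)), c(0.5, 0.5))
  rt <- 0.00198717 * 310.15
  p <- equilibriumDistribution(c(0, rt * log(2)))
  expect_equal(p, c(2 / 3, 1 / 3), tolerance = 1e-12)

  cl <- mkCoarse(data.frame(structure = c("a", "b", "c"),
                            energy = c(-2, -1, -3), occupancy = c(1, 0, 0)),
                 data.frame(from = c("a", "b"), to = c("b", "c"),
                            saddle = c(0.5, 1)))
  R <- buildRateMatrix(cl, k0 = 1e5)
  p <- equilibriumDistribution(c(-2, -1, -3), R = R, tol = 1e-9)
  expect_lt(max(abs(R %*% p)) / max(abs(R)), 1e-9)

  # a detailed-balance violation is reported, not silently accepted
  Rbad <- R; Rbad[2, 1] <- Rbad[2, 1] * 3; Rbad[1, 1] <- Rbad[1, 1] - 2 * R[2, 1]
  expect_error(equilibriumDistribution(c(-2, -1, -3), R = Rbad, tol = 1e-9),
               "detailed-balance")
})

test_that("propagation solves the two-state system to closed-form accuracy", {
  # zero generator: nothing moves
  R0 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  P <- propagateOccupancies(R0, c(0.3, 0.7), c(0, 1, 10))
  expect_equal(unname(P[3, ]), c(0.3, 0.7))

  k12 <- 40; k21 <- 10
  R <- matrix(c(-k12, k12, k21, -k21), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  p0 <- c(1, 0)
  ts <- c(0.001, 0.01, 0.1, 1)
  P <- propagateOccupancies(R, p0, ts)
  pinf <- k21 / (k12 + k21)
  analytic <- pinf + (1 - pinf) * exp(-(k12 + k21) * ts)
  expect_equal(unname(P[, 1]), analytic, tolerance = 1e-9)
})

test_that("eigendecomposition and Pade routes agree on random systems", {
  set.seed(3)
  for (rep in 1:10) {
    m <- 10L
    E <- stats::runif(m, -4, 0)
    rt <- 0.00198717 * 310.15
    R <- matrix(0, m, m)
    for (a in 1:(m - 1)) {   # random connected detailed-balance chain + extras
      b <- a + 1L
      sad <- max(E[a], E[b]) + stats::rexp(1)
      R[b, a] <- 1e3 * exp(-(sad - E[a]) / rt)
      R[a, b] <- 1e3 * exp(-(sad - E[b]) / rt)
    }
    diag(R) <- -colSums(R)
    p0 <- stats::runif(m); p0 <- p0 / sum(p0)
    ts <- 10^seq(-4, 1, length.out = 12)
    Pe <- propagateOccupancies(R, p0, ts, method = "eigen")
    Pp <- propagateOccupancies(R, p0, ts, method = "pade")
    expect_lt(max(abs(Pe - Pp)), 1e-8)
    expect_equal(rowSums(Pe), rep(1, length(ts)), tolerance = 1e-9)
    # long-time limit is the Boltzmann distribution
    lam2 <- sort(eigen(R, only.values = TRUE)$values, decreasing = TRUE)[2]
    Pl <- propagateOccupancies(R, p0, 100 / abs(Re(lam2)))
    expect_lt(sum(abs(Pl[1, ] - equilibriumDistribution(E))) / 2, 1e-6)
  }
})

test_that("the free-energy functional relaxes monotonically", {
  set.seed(9)
  rt <- 0.00198717 * 310.15
  m <- 6L
  E <- stats::runif(m, -3, 0)
  R <- matrix(0, m, m)
  for (a in 1:(m - 1)) {
    sad <- max(E[a], E[a + 1]) + stats::rexp(1)
    R[a + 1, a] <- 1e3 * exp(-(sad - E[a]) / rt)
    R[a, a + 1] <- 1e3 * exp(-(sad - E[a + 1]) / rt)
  }
  diag(R) <- -colSums(R)
  p0 <- c(1, rep(0, m - 1))
  ts <- 10^seq(-5, 2, length.out = 40)
  P <- propagateOccupancies(R, p0, ts)
  Ffun <- apply(P, 1, function(p) {
    nz <- p > 0
    sum(p[nz] * (E[nz] + rt * log(p[nz])))
  })
  expect_true(all(diff(Ffun) <= 1e-8))
})

test_that("propagation matches a stochastic simulation of the same chain", {
  set.seed(15)
  R <- matrix(c(-30, 30, 12, -12), 2, dimnames = list(NULL, c("a", "b")))
  p0 <- c(1, 0)
  tmax <- 0.05
  det <- propagateOccupancies(R, p0, tmax)[1, ]
  ntraj <- 10000L
  sto <- gillespieChain(R, p0, tmax, ntraj)
  sig <- sqrt(pmax(sto * (1 - sto), 1e-12) / ntraj)
  expect_true(all(abs(det - sto) <= 3 * sig + 1e-12))
})

test_that("look-ahead horizons follow the transcription schedule", {
  g <- lookaheadTimes(50, 50, tExt = 0.04, tEnd = 60)
  expect_equal(g@t8, 60)
  g <- lookaheadTimes(40, 50, tExt = 0.04, tEnd = 60)
  expect_equal(g@t1, 0.04)
  expect_equal(g@t8, 0.4, tolerance = 1e-12)
  g <- lookaheadTimes(40, 50, tExt = 0.04, tEnd = 60,
                      pauseSites = c("43" = 2))
  expect_equal(g@t8, 0.4 + 2, tolerance = 1e-12)
  # a pause at the current position extends the linear regime instead
  g <- lookaheadTimes(43, 50, tExt = 0.04, tEnd = 60,
                      pauseSites = c("43" = 2))
  expect_equal(g@t1, 2.04)
  tp <- gridTimes(lookaheadTimes(40, 50, tExt = 0.04, tEnd = 60))
  expect_equal(max(tp$linear), 0.04)
  expect_equal(max(tp$log), 0.4, tolerance = 1e-12)
  expect_true(all(tp$log > 0.04))
})
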