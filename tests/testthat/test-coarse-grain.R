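test_that("a landscape of delta-minima is left unchanged", {
  nodes <- data.frame(structure = c("a1", "a2", "a3"),
                      energy = c(-3, -2, -1),
                      occupancy = c(0.5, 0.3, 0.2))
  edges <- data.frame(from = c("a1", "a2"), to = c("a2", "a3"),
                      saddle = c(5, 5))
  cl <- coarseGrain(asLandscape(list(nodes = nodes, edges = edges)),
                    delta = 1)
  expect_equal(cl@nodes$structure, nodes$structure)
  expect_equal(cl@nodes$occupancy, nodes$occupancy)
  expect_equal(nrow(cl@edges), 2L)
})

test_that("coarse graining a 1-D chain reproduces the path flooding result", {
  set.seed(101)
  for (rep in 1:40) {
    m <- sample(6:20, 1L)
    e <- round(stats::runif(m, -4, 4), 2)
    delta <- stats::runif(1, 0.3, 3)
    labs <- sprintf("c%02d", seq_len(m))
    occ <- rep(1 / m, m)
    edges <- data.frame(from = labs[-m], to = labs[-1L],
                        saddle = pmax(e[-m], e[-1L]))
    nodes <- data.frame(structure = labs, energy = e, occupancy = occ)
    cl <- coarseGrain(asLandscape(list(nodes = nodes, edges = edges)), delta)
    # graph-level delta-minimum definition oracle on the chain
    expect_setequal(cl@nodes$structure,
                    bruteGraphDeltaMinima(nodes, edges, delta))
    # interior delta-minima agree with path flooding (flooding additionally
    # keeps the externally supplied endpoints by convention)
    fl <- floodPath(e, delta)
    expect_setequal(intersect(cl@nodes$structure, labs[-c(1L, m)]),
                    labs[setdiff(fl@minima, c(1L, m))])
    expect_equal(sum(cl@nodes$occupancy), 1, tolerance = 1e-12)
  }
})

test_that("a delta above the energy span leaves a single representative", {
  ls <- randomLandscape(10)
  cl <- coarseGrain(asLandscape(ls), delta = 1e3)
  expect_equal(nrow(cl@nodes), 1L)
  expect_equal(cl@nodes$energy, min(ls$nodes$energy))
  expect_equal(cl@nodes$occupancy, 1, tolerance = 1e-12)
})

test_that("occupancy is conserved on many random landscapes", {
  set.seed(77)
  for (rep in 1:1000) {
    ls <- randomLandscape(sample(3:12, 1L))
    cl <- coarseGrain(asLandscape(ls), delta = stats::runif(1, 0.1, 4))
    expect_equal(sum(cl@nodes$occupancy), 1, tolerance = 1e-12)
    # saddles still dominate endpoint energies
    if (nrow(cl@edges)) {
      en <- setNames(cl@nodes$energy, cl@nodes$structure)
      expect_true(all(cl@edges$saddle + 1e-9 >=
                        pmax(en[cl@edges$from], en[cl@edges$to])))
    }
  }
})

test_that("coarse graining is idempotent and monotone in delta", {
  set.seed(13)
  for (rep in 1:50) {
    ls <- randomLandscape(sample(5:15, 1L))
    L <- asLandscape(ls)
    delta <- stats::runif(1, 0.2, 3)
    cl1 <- coarseGrain(L, delta)
    cl2 <- coarseGrain(cl1, delta)
    expect_equal(cl2@nodes, cl1@nodes)
    expect_equal(cl2@edges[order(cl2@edges$from, cl2@edges$to), ],
                 cl1@edges[order(cl1@edges$from, cl1@edges$to), ],
                 ignore_attr = TRUE)
    # representative count non-increasing in delta
    clBig <- coarseGrain(L, delta * 2)
    expect_lte(nrow(clBig@nodes), nrow(cl1@nodes))
  }
})

test_that("representatives equal the delta-minimum minimax oracle on random graphs", {
  set.seed(31)
  for (rep in 1:1000) {
    ls <- randomLandscape(sample(4:20, 1L))
    delta <- stats::runif(1, 0.2, 3)
    cl <- coarseGrain(asLandscape(ls), delta)
    oracle <- bruteGraphDeltaMinima(ls$nodes, ls$edges, delta)
    expect_setequal(cl@nodes$structure, oracle)
  }
})

test_that("the delta -> 0 limit keeps every local minimum", {
  set.seed(57)
  for (rep in 1:100) {
    # elementary-move-like landscape: saddle = max endpoint energy, so the
    # barrier out of a non-minimum is exactly zero
    ls <- randomLandscape(sample(4:12, 1L), zeroBarrier = TRUE)
    cl <- coarseGrain(asLandscape(ls), delta = 1e-9)
    en <- setNames(ls$nodes$energy, ls$nodes$structure)
    adj <- list()
    for (r in seq_len(nrow(ls$edges))) {
      adj[[ls$edges$from[r]]] <- c(adj[[ls$edges$from[r]]], ls$edges$to[r])
      adj[[ls$edges$to[r]]] <- c(adj[[ls$edges$to[r]]], ls$edges$from[r])
    }
    localMin <- ls$nodes$structure[vapply(ls$nodes$structure, function(x)
      all(en[adj[[x]]] >= en[[x]]), TRUE)]
    expect_setequal(cl@nodes$structure, localMin)
  }
})

test_that("transient occupancy flows to the minimal-saddle neighbors", {
  # b is transient; its two neighbors are reached over equal minimal saddles
  nodes <- data.frame(structure = c("a", "b", "c"),
                      energy = c(-1, 0, -2),
                      occupancy = c(0, 1, 0))
  edges <- data.frame(from = c("a", "b"), to = c("b", "c"), saddle = c(0.2, 0.2))
  cl <- coarseGrain(asLandscape(list(nodes = nodes, edges = edges)), delta = 1)
  expect_setequal(cl@nodes$structure, c("a", "c"))
  expect_equal(cl@nodes$occupancy[cl@nodes$structure == "a"], 0.5)
  expect_equal(cl@nodes$occupancy[cl@nodes$structure == "c"], 0.5)
  # both neighbors were fast-reachable, so they are now connected through b
  expect_equal(nrow(cl@edges), 1L)
  expect_equal(cl@edges$saddle, 0.2)
  expect_named(cl@basinMap, "b")
})
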