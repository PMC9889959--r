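vm <- viennaModel()

test_that("fraying constraints open exterior helices as specified", {
  # no structure: a single all-free constraint
  expect_equal(frayingConstraints("GGGAAACCCAAA", strrep(".", 11), 12),
               strrep(".", 12))

  # one exterior helix: single-helix constraint and all-open coincide
  s <- "GGGGAAAACCCCAAAAGGGGAAAACCCCA"
  parent <- "((((....))))................"
  cs <- frayingConstraints(s, parent, 29, mfree = 6L)
  expect_length(cs, 1L)
  expect_equal(cs, strrep(".", 29))

  # two exterior helices: one constraint per helix plus all-open
  parent2 <- "((((....))))....((((....))))"
  cs2 <- frayingConstraints(s, parent2, 29, mfree = 6L)
  expect_length(cs2, 3L)
  expect_true(strrep(".", 29) %in% cs2)  # all helices open
  expect_true("((((xxxx))))................." %in% cs2)
  expect_true(".................((((xxxx))))" %in% sub("^.", ".", cs2) ||
              "................((((xxxx))))." %in% cs2)

  # mfree deepening: opening the outer 2-bp stack frees only 5 nucleotides,
  # so the enclosed helix is opened as well
  s3 <- "GGAGGGGAAAAACCCCCC"
  parent3 <- "((.((((.....))))))"
  expect_length(validateStructure(s3, parent3), 0L)
  cs3 <- frayingConstraints(s3, parent3, 18, mfree = 6L)
  expect_equal(cs3, strrep(".", 18))
  # with a small mfree the enclosed helix stays closed
  cs3b <- frayingConstraints(s3, parent3, 18, mfree = 3L)
  expect_equal(cs3b, "...((((xxxxx)))).." )
})

test_that("candidate search keeps parents, improvements and the MFE", {
  s <- "GGGGAAAACCCCAAAAGGGG"
  mfe <- constrainedMFE(vm, s)$structure
  # fixed point: the MFE structure as single parent
  cands <- findCandidates(vm, s, mfe, nchar(s))
  expect_true(mfe %in% cands)
  # a parent that frays into a better refold contributes it
  weak <- "((......))((......))"
  expect_length(validateStructure(s, weak), 0L)
  cands2 <- findCandidates(vm, s, weak, nchar(s))
  expect_true(weak %in% cands2)
  expect_true(mfe %in% cands2)  # unconstrained MFE always returned
  eW <- freeEnergy(vm, s, weak)
  extra <- setdiff(cands2, c(weak, mfe))
  if (length(extra))
    expect_true(all(freeEnergy(vm, s, extra) <= eW + 0.01 + 1e-9))
})

test_that("guide edges follow the worked three-structure example", {
  x <- "..((...))"; y <- "..(....)."; z <- "(((...)))"
  ed <- guideEdges(c(x, y, z))
  key <- paste(ed$from, ed$to, ed$kind)
  expect_setequal(key, c("1 2 guide", "2 3 guide", "1 3 shortcut"))
})

test_that("the guide graph over a full ensemble is the elementary move set", {
  s <- "GGCAAAAUGCC"
  ens <- enumerateEnsemble(s)
  ed <- guideEdges(ens)
  expect_true(all(ed$kind == "guide"))
  dd <- vapply(seq_len(nrow(ed)), function(r)
    basePairDistance(ens[ed$from[r]], ens[ed$to[r]]), 0L)
  expect_true(all(dd == 1L))
  # every elementary move appears as a guide edge
  for (x in ens) {
    for (y in elementaryNeighbors(s, x)) {
      a <- match(x, ens); b <- match(y, ens)
      expect_true(any((ed$from == min(a, b)) & (ed$to == max(a, b))))
    }
  }
})

test_that("Arrhenius rates reduce to the Metropolis rule for single moves", {
  expect_equal(rateFromSaddle(-2, -2, k0 = 1e5), 1e5)
  R <- 0.00198717
  expect_equal(rateFromSaddle(0, 1, k0 = 1e5, temperature = 37),
               1e5 * exp(-1 / (R * 310.15)))
  expect_error(rateFromSaddle(0, -0.5, k0 = 1e5), "saddle")

  # saddle of a single base-pair move = max endpoint energy -> Metropolis
  s <- "GGGAAACCC"
  x <- "(((...)))"; y <- "((.....))"
  ex <- freeEnergy(vm, s, x); ey <- freeEnergy(vm, s, y)
  sad <- max(freeEnergy(vm, s, c(x, y)))
  kf <- rateFromSaddle(ex, sad, 1e5)
  kb <- rateFromSaddle(ey, sad, 1e5)
  rt <- 0.00198717 * 310.15
  expect_equal(kf, 1e5 * min(1, exp(-(ey - ex) / rt)), tolerance = 1e-12)
  expect_equal(kb, 1e5 * min(1, exp(-(ex - ey) / rt)), tolerance = 1e-12)
})

test_that("expansion starts from the MFE with full occupancy", {
  ls0 <- emptyLandscape("GGGAAACCC")
  ls1 <- expandLandscape(ls0, NULL, 1L, vm, delta = 1)
  expect_equal(nrow(ls1@nodes), 1L)
  expect_equal(ls1@nodes$occupancy, 1)
  expect_equal(ls1@nodes$structure, strrep(".", 9))
  expect_equal(nrow(ls1@edges), 0L)
})

test_that("expanded landscapes are connected with detailed-balance rates", {
  s <- "GGGGAAAACCCCAAAAGGGG"
  ls0 <- emptyLandscape(s)
  parents <- data.frame(
    structure = c("((((....))))........", "........((((....))))"),
    occupancy = c(0.7, 0.3))
  ls1 <- expandLandscape(ls0, parents, nchar(s), vm, delta = 1)
  expect_gte(nrow(ls1@nodes), 2L)
  expect_equal(sum(ls1@nodes$occupancy), 1, tolerance = 1e-12)

  # connectivity: undirected reachability over the edge set
  nd <- ls1@nodes$structure
  adj <- lapply(setNames(vector("list", length(nd)), nd), identity)
  for (r in seq_len(nrow(ls1@edges))) {
    adj[[ls1@edges$from[r]]] <- c(adj[[ls1@edges$from[r]]], ls1@edges$to[r])
    adj[[ls1@edges$to[r]]] <- c(adj[[ls1@edges$to[r]]], ls1@edges$from[r])
  }
  seen <- nd[1L]; frontier <- nd[1L]
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  expect_setequal(seen, nd)

  # every edge satisfies saddle >= max endpoint energy, hence exact detailed
  # balance of the Arrhenius rates
  en <- setNames(ls1@nodes$energy, nd)
  rt <- 0.00198717 * 310.15
  for (r in seq_len(nrow(ls1@edges))) {
    a <- ls1@edges$from[r]; b <- ls1@edges$to[r]; sdl <- ls1@edges$saddle[r]
    expect_gte(sdl, max(en[a], en[b]) - 1e-9)
    kf <- rateFromSaddle(en[[a]], sdl, 1e5)
    kb <- rateFromSaddle(en[[b]], sdl, 1e5)
    expect_equal(kf / kb, exp(-(en[[b]] - en[[a]]) / rt), tolerance = 1e-9)
  }

  # determinism: a fresh expansion gives bit-identical results
  ls2 <- expandLandscape(emptyLandscape(s), parents, nchar(s), vm, delta = 1)
  expect_identical(ls1@nodes, ls2@nodes)
  expect_identical(ls1@edges, ls2@edges)
})

test_that("path decomposition inserts interior minima as landscape nodes", {
  # competing helices force a compound transition at small delta
  s <- "GGGGAAAACCCCAAAAGGGG"
  ls0 <- emptyLandscape(s)
  parents <- data.frame(
    structure = c("((((....))))........", "........((((....))))"),
    occupancy = c(0.5, 0.5))
  lsBig <- expandLandscape(emptyLandscape(s), parents, nchar(s), vm,
                           delta = 10)
  lsSmall <- expandLandscape(ls0, parents, nchar(s), vm, delta = 0.1)
  expect_gte(nrow(lsSmall@nodes), nrow(lsBig@nodes))
})
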