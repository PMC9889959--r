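vm <- viennaModel()

test_that("free energies match the reference command-line evaluator", {
  cases <- data.frame(
    seq = c("GGGAAACCC", "GGGAAACCC", "GCGCUUCGGCGC", "GGCGAAAACGCCAAAA"),
    db  = c("(((...)))", ".........", "((((....))))", "((((....))))...."))
  inp <- paste(rbind(cases$seq, cases$db), collapse = "\n")
  out <- system2("RNAeval", input = inp, stdout = TRUE)
  ref <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)$", "\\1",
                        grep("\\)$", out, value = TRUE)))
  got <- vapply(seq_len(nrow(cases)), function(k)
    freeEnergy(vm, cases$seq[k], cases$db[k]), 0)
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("the open chain is the zero reference state in both backends", {
  expect_equal(freeEnergy(vm, "GGGAAACCC", "........."), 0)
  expect_equal(freeEnergy(toy, "GGGAAACCC", "........."), 0)
})

test_that("energies follow the full-length evaluation convention", {
  s <- "GGGAAACCCAAAA"
  # a prefix structure keeps its stored energy as the transcript grows:
  # identical padded strings evaluate identically, and differ from the
  # prefix-only evaluation just by exterior/dangle terms
  ePad <- freeEnergy(vm, s, "(((...)))")
  expect_equal(ePad, freeEnergy(vm, s, "(((...)))...."))
  ePrefix <- freeEnergy(vm, "GGGAAACCC", "(((...)))")
  expect_false(isTRUE(all.equal(ePad, ePrefix)))  # dangle terms differ
})

test_that("constrained folding honors constraints and reports infeasibility", {
  s <- "GGGAAACCCAAA"
  # all positions forced unpaired
  res <- constrainedMFE(vm, s, upTo = 12, constraint = strrep("x", 12),
                        enforce = TRUE)
  expect_equal(res$structure, strrep(".", 12))
  expect_equal(res$energy, 0)

  # unconstrained equals the engine's global MFE
  out <- system2("RNAfold", args = "--noPS", input = s, stdout = TRUE)
  ref <- strsplit(out[2], " ")[[1]][1]
  expect_equal(constrainedMFE(vm, s)$structure, ref)

  # enforcing the MFE's own pairs is a fixed point
  mfe <- constrainedMFE(vm, s)
  res <- constrainedMFE(vm, s, constraint = mfe$structure, enforce = TRUE)
  expect_equal(res$structure, mfe$structure)
  expect_equal(res$energy, mfe$energy)

  # unsatisfiable pair (hairpin loop below three nucleotides) -> explicit
  # infeasibility signal, not a silently different structure
  res <- constrainedMFE(vm, "GGGGAAACCCC", upTo = 11,
                        constraint = "(..).......", enforce = TRUE)
  expect_false(res$feasible)
})

test_that("constraints only restrict: constrained MFE energy is never lower", {
  set.seed(11)
  for (rep in 1:10) {
    s <- randomSequences(1, 30)
    e0 <- constrainedMFE(vm, s)$energy
    cs <- paste(sample(c(".", "x"), 30, replace = TRUE, prob = c(.7, .3)),
                collapse = "")
    res <- constrainedMFE(vm, s, constraint = cs, enforce = TRUE)
    if (res$feasible) expect_gte(res$energy, e0 - 1e-9)
  }
})

test_that("union-constrained MFE equals the brute-force subset minimum", {
  set.seed(3)
  checked <- 0L
  for (rep in 1:40) {
    s <- randomSequences(1, 18)
    a <- constrainedMFE(vm, s)$structure
    b <- constrainedMFE(vm, s, upTo = 12)$structure
    if (a == b) next
    if (basePairDistance(a, b) > 12L) next
    z <- directPathMFE(vm, s, a, b)
    cand <- unique(rbind(parseDotBracket(a), parseDotBracket(b)))
    sets <- CoTransFold:::.enumeratePairSubsets(cand)
    dbs <- vapply(sets, function(p) dotBracket(p, nchar(s)), "")
    es <- freeEnergy(vm, s, dbs)
    expect_equal(z$energy, min(es), tolerance = 1e-9)
    expect_true(all(apply(parseDotBracket(z$structure), 1L, function(pr)
      any(cand[, 1L] == pr[1L] & cand[, 2L] == pr[2L]))))
    checked <- checked + 1L
  }
  expect_gte(checked, 10L)

  # endpoints identical: the union MFE is that structure or better within it
  s <- "GGGAAACCC"
  z <- directPathMFE(vm, s, "(((...)))", "(((...)))")
  expect_equal(z$structure, "(((...)))")
})

test_that("the toy backend agrees with its exhaustive definitions", {
  s <- "GGCGAAAACGCC"
  ens <- enumerateEnsemble(s)
  es <- freeEnergy(toy, s, ens)
  mfe <- constrainedMFE(toy, s)
  expect_equal(mfe$energy, min(es))
  expect_equal(mfe$structure, ens[order(es, ens)][1])
  # constrained fold respects enforce semantics
  res <- constrainedMFE(toy, s, constraint = "((........))", enforce = TRUE)
  expect_true(res$feasible)
  pt <- pairTable(res$structure)
  expect_equal(pt[1], 12L)
  expect_equal(pt[2], 11L)
})
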