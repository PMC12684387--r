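test_that("unfoldable and two-state sequences give the expected MFE", {
  p <- defaultEnergyParams()
  st <- mfeFold("AAAA", p)
  expect_equal(foldEnergy(st), 0)
  expect_equal(nrow(basePairs(st)), 0L)
  expect_equal(dotBracket(st), "....")
  # hairpin formation is decided by the sign of its only loop energy
  pNeg <- p; pNeg@hairpinInit[4] <- -1
  expect_equal(nrow(basePairs(mfeFold("GAAAAC", pNeg))), 1L)
  expect_equal(foldEnergy(mfeFold("GAAAAC", pNeg)), -1)
  expect_equal(nrow(basePairs(mfeFold("GAAAAC", p))), 0L)  # +5.6 beats 0
})

test_that("MFE equals the enumerated minimum on short random sequences", {
  set.seed(61)
  p <- gtParams()
  for (rep in 1:12) {
    n <- sample(10:16, 1)
    s <- randomModSeq(n, modProb = 0.2)
    ens <- enumerateStructures(s, p)
    om <- oracleMfe(s, p, ensemble = ens)
    st <- mfeFold(s, p)
    expect_identical(foldEnergy(st), om$energy)
    # and no enumerated structure beats it
    en <- vapply(ens, function(x) x$energy, 0)
    expect_lte(foldEnergy(st), min(en) + 1e-12)
    # dot-bracket round-trips to the same pair set
    rt <- parseDotBracket(dotBracket(st))
    expect_equal(basePairs(rt), basePairs(st), ignore_attr = TRUE)
  }
})

test_that("at low temperature the ensemble concentrates on the MFE pairs", {
  p <- gtParams()
  s <- "GGGGC6AAAAAUGCCCC"
  st <- mfeFold(s, p)
  expect_gt(nrow(basePairs(st)), 2L)
  # beta is raised only moderately: the partition function is computed
  # without rescaling, so extreme beta would overflow
  cold <- p; cold@beta <- p@beta * 8
  P <- bppMatrix(bpp(s, cold))
  for (q in seq_len(nrow(basePairs(st))))
    expect_gt(P[basePairs(st)[q, 1], basePairs(st)[q, 2]], 0.99)
  expect_lt(sum(P[upper.tri(P)]) - nrow(basePairs(st)), 0.05)
})

test_that("traceback is deterministic and respects nesting", {
  set.seed(62)
  p <- gtParams()
  for (rep in 1:6) {
    s <- randomModSeq(40, modProb = 0.1)
    st1 <- mfeFold(s, p); st2 <- mfeFold(s, p)
    expect_identical(basePairs(st1), basePairs(st2))
    prs <- basePairs(st1)
    if (nrow(prs) >= 2) {
      for (a in seq_len(nrow(prs) - 1)) for (b in (a + 1):nrow(prs)) {
        i <- prs[a, 1]; j <- prs[a, 2]; h <- prs[b, 1]; l <- prs[b, 2]
        crossing <- (i < h && h < j && j < l) || (h < i && i < l && l < j)
        expect_false(crossing)
      }
      expect_equal(anyDuplicated(c(prs)), 0L)
    }
  }
})
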