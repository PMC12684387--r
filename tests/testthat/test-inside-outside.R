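test_that("degenerate sequences have a trivial ensemble", {
  p <- defaultEnergyParams()
  # no pair possible
  r <- bpp("AAAA", p)
  expect_equal(partitionFunction(r), 1.0)
  expect_equal(max(bppMatrix(r)), 0)
  expect_equal(mbpp(r), rep(0, 4))
  # the only candidate pair violates the minimum loop
  expect_equal(partitionFunction(bpp("ACGU", p)), 1.0)
})

test_that("two-state hairpin matches the closed form", {
  p <- defaultEnergyParams()
  x <- exp(-p@beta * hairpinEnergy("GAAAAC", 1, 6, p))
  r <- bpp("GAAAAC", p)
  expect_equal(partitionFunction(r), 1 + x)
  expect_equal(bppMatrix(r)[1, 6], x / (1 + x))
  # outside weight of the outermost pair is 1 (empty exterior)
  tabs <- insideOutside("GAAAAC", p)$tables
  expect_equal(tabs$Wb[1, 6], 1.0)
})

test_that("DP tables satisfy their structural invariants", {
  set.seed(21)
  p <- gtParams()
  for (rep in 1:5) {
    s <- randomModSeq(20)
    io <- insideOutside(s, p)
    Zt <- io$tables$Z
    expect_true(all(Zt[upper.tri(Zt, diag = TRUE)] >= 1))
    # Zb vanishes on disallowed pairs and undersized loops
    ch <- strsplit(s, "")[[1]]
    for (i in 1:19) for (j in (i + 1):20)
      if (!isPairable(ch[i], ch[j]) || j - i - 1 < p@minLoop)
        expect_identical(io$tables$Zb[i, j], 0)
    expect_true(all(is.finite(io$tables$Wb)))
    # probability mass: every base is paired with probability <= 1
    expect_true(all(io$mbpp <= 1 + 1e-12))
    expect_true(all(io$P >= 0 & io$P <= 1 + 1e-12))
  }
})

test_that("DP matches the enumeration oracle on short random sequences", {
  set.seed(5)
  p <- gtParams()
  for (rep in 1:12) {
    n <- sample(10:14, 1)
    s <- randomModSeq(n, modProb = 0.15)
    ens <- enumerateStructures(s, p)
    ob <- oracleBpp(s, p, ensemble = ens)
    r <- bpp(s, p)
    expect_lt(abs(partitionFunction(r) - ob$Z) / ob$Z, 1e-9)
    expect_lt(max(abs(bppMatrix(r) - ob$P)), 1e-9)
    expect_lt(max(abs(mbpp(r) - ob$mbpp)), 1e-9)
  }
})

test_that("expected pair count agrees between DP and enumeration", {
  set.seed(6)
  p <- gtParams()
  s <- randomModSeq(14, modProb = 0.2)
  ens <- enumerateStructures(s, p)
  w <- vapply(ens, function(st) exp(-p@beta * st$energy), 0)
  npairs <- vapply(ens, function(st) nrow(st$pairs), 0L)
  expected <- sum(npairs * w) / sum(w)
  P <- bppMatrix(bpp(s, p))
  expect_equal(sum(P[upper.tri(P)]), expected, tolerance = 1e-9)
})

test_that("lowering a stack energy raises the probability of its pairs", {
  # two-state-with-stack construct: helix (2,9)/(3,8) carrying 6CUG
  p1 <- gtParams()
  th <- gtTheta(); th["6CUG"] <- th["6CUG"] - 1
  p2 <- defaultEnergyParams(th)
  s <- "A6CAAAAGUU"
  expect_gt(bppMatrix(bpp(s, p2))[2, 9], bppMatrix(bpp(s, p1))[2, 9])
  expect_gt(bppMatrix(bpp(s, p2))[3, 8], bppMatrix(bpp(s, p1))[3, 8])
})

test_that("sequences longer than the no-rescaling cap are refused", {
  expect_error(bpp(strrep("GC", 101)), "longer than 200")
})
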