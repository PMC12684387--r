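test_that("the minimum design set is 135 x 50 nt covering all classes", {
  ds <- designMinimumSet(seed = 1)
  expect_equal(nrow(ds), 135L)
  expect_true(all(nchar(ds$seq) == 50L))
  expect_setequal(unique(ds$stackName), thetaNames())
  expect_equal(as.vector(table(ds$stackName)), rep(9L, 15))
  expect_true(all(grepl("6", ds$seq)))
  # determinism
  expect_identical(ds, designMinimumSet(seed = 1))
  expect_false(identical(ds$seq, designMinimumSet(seed = 2)$seq))
})

test_that("stems pair under the rules and host the designated stack", {
  ds <- designMinimumSet(seed = 4)
  p <- gtParams()
  for (q in sample(nrow(ds), 20)) {
    ch <- strsplit(ds$seq[q], "")[[1]]
    for (t in 1:10)
      expect_true(isPairable(ch[10 + t], ch[41 - t]))
    # the designated stack sits at stem offsets (position, position+1)
    pos <- ds$position[q]
    g <- twoLoopThetaGrad(ds$seq[q], 10 + pos, 41 - pos,
                          11 + pos, 40 - pos, p)
    expect_equal(unname(g[[ds$stackName[q]]]), 1)
  }
})

test_that("the designed stem dominates the noiseless ensemble for most draws", {
  # soft check on the design intent: the stem should be the MFE helix
  ds <- designMinimumSet(seed = 1, stackNames = c("6CUG", "UG6C"))
  p <- gtParams()
  ok <- vapply(seq_len(nrow(ds)), function(q) {
    prs <- basePairs(mfeFold(ds$seq[q], p))
    stem <- cbind(10 + (1:10), 41 - (1:10))
    sum(paste(stem[, 1], stem[, 2]) %in% paste(prs[, 1], prs[, 2])) >= 8
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("random modified designs carry the requested modification load", {
  ds <- designRandomModified(5, length = 150, nMods = 8, seed = 9)
  expect_true(all(nchar(ds$seq) == 150L))
  n6 <- vapply(strsplit(ds$seq, ""), function(x) sum(x == "6"), 0L)
  expect_true(all(n6 == 8L))
  # no modifications requested: canonical only
  ds0 <- designRandomModified(3, length = 60, nMods = 0, seed = 9)
  expect_false(any(grepl("6", ds0$seq)))
  expect_identical(designRandomModified(5, 150, 8, seed = 9), ds)
})

test_that("fully modified designs have no adenosine left and are reversible", {
  ds <- designFullyModified(5, length = 80, seed = 11)
  expect_false(any(grepl("A", ds$seq, fixed = TRUE)))
  expect_identical(gsub("6", "A", ds$seq, fixed = TRUE), ds$canonical)
  expect_identical(ds, designFullyModified(5, length = 80, seed = 11))
})

test_that("evaluation cohorts come in the standard modification groups", {
  for (m in c(1L, 2L, 4L, 8L)) {
    ds <- designEvalRandom(4, length = 50, nMods = m, seed = m)
    n6 <- vapply(strsplit(ds$seq, ""), function(x) sum(x == "6"), 0L)
    expect_true(all(n6 == m))
    expect_true(all(nchar(ds$seq) == 50L))
  }
})
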