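test_that("sequences without m6A have identically zero gradients", {
  set.seed(31)
  p <- gtParams()
  s <- randomCanonSeq(25)
  expect_false(any(bppGradients(s, p)$active))   # auto-detection: none
  g <- bppGradients(s, p, which = 1:15, withTables = TRUE)
  for (k in 1:15) {
    expect_equal(max(abs(g$perTheta[[k]]$dP)), 0)
    expect_equal(max(abs(g$perTheta[[k]]$tables$dWb)), 0)
    expect_equal(g$perTheta[[k]]$dZ, 0)
  }
  # two-state hairpin (no stack at all): dZ_{1,N} = 0
  g2 <- bppGradients("GAAAAC", p, which = 1:15)
  expect_equal(g2$perTheta[[1]]$dZ, 0)
})

test_that("dZ matches the enumeration oracle and dZb vanishes with Zb", {
  set.seed(32)
  p <- gtParams()
  for (rep in 1:8) {
    n <- sample(12:16, 1)
    s <- randomModSeq(n, modProb = 0.2)
    ens <- enumerateStructures(s, p)
    gz <- oracleGradZ(s, p, ensemble = ens)
    g <- bppGradients(s, p, which = 1:15, withTables = TRUE)
    io <- insideOutside(s, p)
    for (k in 1:15) {
      expect_lt(abs(g$perTheta[[k]]$dZ - gz[k]) / (abs(gz[k]) + 1e-12),
                1e-7)
      expect_true(all(g$perTheta[[k]]$tables$dZb[io$tables$Zb == 0] == 0))
    }
  }
})

test_that("dWb at the outermost pair is zero (parameter-free exterior)", {
  p <- gtParams()
  s <- "6GGAAAACCU"                    # (1,10) pairable 6-U
  g <- bppGradients(s, p, withTables = TRUE)
  for (k in which(g$active))
    expect_equal(g$perTheta[[k]]$tables$dWb[1, 10], 0)
})

test_that("analytic dP and dWb agree with central finite differences", {
  set.seed(33)
  p <- gtParams()
  h <- 1e-4
  for (rep in 1:6) {
    n <- sample(14:20, 1)
    s <- randomModSeq(n, modProb = 0.2)
    g <- bppGradients(s, p, withTables = TRUE)
    for (k in which(g$active)) {
      thp <- gtTheta(); thp[k] <- thp[k] + h
      thm <- gtTheta(); thm[k] <- thm[k] - h
      pp <- defaultEnergyParams(thp); pm <- defaultEnergyParams(thm)
      fdP <- (bppMatrix(bpp(s, pp)) - bppMatrix(bpp(s, pm))) / (2 * h)
      an <- g$perTheta[[k]]$dP
      expect_lt(max(abs(an - fdP) / (abs(an) + 1e-12)), 1e-5)
      fdW <- (insideOutside(s, pp)$tables$Wb -
              insideOutside(s, pm)$tables$Wb) / (2 * h)
      anW <- g$perTheta[[k]]$tables$dWb
      expect_lt(max(abs(anW - fdW) / (abs(anW) + 1e-12)), 1e-5)
    }
  }
})

test_that("joint gradients equal one-at-a-time gradients and leave forward tables untouched", {
  set.seed(34)
  p <- gtParams()
  s <- randomModSeq(22, modProb = 0.2)
  before <- insideOutside(s, p)
  g <- bppGradients(s, p)                  # all active classes jointly
  for (k in which(g$active)) {
    gk <- bppGradients(s, p, which = k)
    expect_identical(gk$perTheta[[k]]$dP, g$perTheta[[k]]$dP)
    expect_identical(gk$perTheta[[k]]$dmbpp, g$perTheta[[k]]$dmbpp)
  }
  after <- insideOutside(s, p)
  expect_identical(before, after)          # pure-function contract
})

test_that("marginal gradients are the row sums of dP", {
  set.seed(35)
  p <- gtParams()
  s <- randomModSeq(18, modProb = 0.25)
  g <- bppGradients(s, p)
  M <- mbppGradients(s, p)
  for (k in which(g$active))
    expect_equal(M[k, ], rowSums(g$perTheta[[k]]$dP))
  expect_equal(dim(M), c(15L, 18L))
})
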