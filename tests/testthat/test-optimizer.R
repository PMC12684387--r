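test_that("L1 loss on marginals behaves arithmetically", {
  expect_equal(lossL1(c(0.5, 0.2), c(0.5, 0.2)), 0)
  expect_equal(lossL1(c(0.5, 0.2), c(0.3, 0.4)), 0.4)
  set.seed(41)
  a <- runif(10); b <- runif(10); perm <- sample(10)
  expect_equal(lossL1(a[perm], b[perm]), lossL1(a, b))
  expect_error(lossL1(1:3 / 10, 1:4 / 10), "length")
})

test_that("loss gradient vanishes at an exact fit and without m6A", {
  p <- gtParams()
  s <- "A6CAAAAGUUA"
  mb <- mbpp(bpp(s, p))
  g <- lossGradient(s, p, mb)
  expect_equal(g$loss, 0)
  expect_equal(unname(g$grad), rep(0, 15))
  g2 <- lossGradient(randomCanonSeq(20), p, rep(0.5, 20))
  expect_equal(unname(g2$grad), rep(0, 15))
})

test_that("loss gradient matches central finite differences", {
  set.seed(42)
  p <- gtParams()
  init <- defaultEnergyParams(-1)
  h <- 1e-4
  for (rep in 1:4) {
    s <- randomModSeq(25, modProb = 0.2)
    mb <- mbpp(bpp(s, p))
    g <- lossGradient(s, init, mb)
    for (k in which(g$grad != 0)) {
      thp <- theta(init); thp[k] <- thp[k] + h
      thm <- theta(init); thm[k] <- thm[k] - h
      fd <- (lossL1(mb, mbpp(bpp(s, defaultEnergyParams(thp)))) -
             lossL1(mb, mbpp(bpp(s, defaultEnergyParams(thm))))) / (2 * h)
      expect_lt(abs(fd - g$grad[k]) / (abs(fd) + 1e-12), 1e-4)
    }
  }
})

test_that("a single step moves theta toward the ground truth", {
  # designed construct in which 6CUG is the dominant trainable signal
  p <- gtParams()
  s <- designMinimumSet(seed = 3, stackNames = "6CUG", positions = 5)$seq
  mb <- mbpp(bpp(s, p))
  init <- defaultEnergyParams(-1)        # GT 6CUG is -1.79: must decrease
  st <- sgdStep(s, init, mb)
  expect_lt(theta(st$params)[["6CUG"]], -1)
  # zero gradient or zero learning rate leaves theta unchanged
  st0 <- sgdStep(s, p, mbpp(bpp(s, p)))
  expect_equal(theta(st0$params), theta(p))
  stlr <- sgdStep(s, init, mb, lr = 0)
  expect_equal(theta(stlr$params), theta(init))
})

test_that("training bookkeeping: update counts, loss history, determinism", {
  p <- gtParams()
  ds <- designMinimumSet(seed = 2, stackNames = "UA6U", positions = c(4, 5))
  mb <- lapply(ds$seq, function(s) mbpp(bpp(s, p)))
  fit <- trainParams(ds$seq, mb, p, epochs = 5, trace = TRUE)
  expect_equal(updateCount(fit), 5L * nrow(ds))
  expect_equal(nrow(lossHistory(fit)), updateCount(fit))
  expect_equal(max(lossHistory(fit)$epoch), 5L)
  fit2 <- trainParams(ds$seq, mb, p, epochs = 5, trace = TRUE)
  expect_identical(theta(fit), theta(fit2))                # bitwise repeat
  expect_identical(thetaTrajectory(fit), thetaTrajectory(fit2))
  # epochs = 0 returns the initial parameters untouched
  fit0 <- trainParams(ds$seq, mb, p, epochs = 0, initTheta = -1)
  expect_equal(unname(theta(fit0)), rep(-1, 15))
  expect_equal(updateCount(fit0), 0L)
})

test_that("parameters whose stacks never occur stay exactly at the initial value", {
  p <- gtParams()
  # fully modified sequences cannot exercise classes needing unmodified A
  ds <- designFullyModified(4, length = 40, seed = 7)
  mb <- lapply(ds$seq, function(s) mbpp(bpp(s, p)))
  fit <- trainParams(ds$seq, mb, p, epochs = 3, initTheta = -1)
  needA <- grepl("A", thetaNames(), fixed = TRUE)  # classes with unmodified A
  expect_true(all(theta(fit)[needA] == -1))
})

test_that("the divergence guard aborts on runaway parameters", {
  p <- gtParams()
  s <- designMinimumSet(seed = 3, stackNames = "6CUG", positions = 5)$seq
  mb <- mbpp(bpp(s, p))
  # a deliberately absurd step size must trip the guard
  expect_error(
    trainParams(list(s), list(mb), p, epochs = 50, lr = 5e6,
                energyUnit = 1, guard = 50),
    "divergence guard")
})
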