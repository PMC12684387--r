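test_that("pair rules are the eight allowed pairs, closed under reversal", {
  al <- c("A", "C", "G", "U", "6")
  allowed <- c("AU", "UA", "GC", "CG", "GU", "UG", "6U", "U6")
  for (x in al) for (y in al) {
    expect_identical(isPairable(x, y), paste0(x, y) %in% allowed)
    expect_identical(isPairable(x, y), isPairable(y, x))
  }
})

test_that("every m6A-containing stack geometry resolves to exactly one of the 15 classes", {
  al <- c("A", "C", "G", "U", "6")
  hits <- character(0)
  for (a in al) for (b in al) for (c in al) for (d in al) {
    if (!isPairable(a, c) || !isPairable(b, d)) next
    k <- stackGrad:::.stackClass(a, b, c, d)
    if (any(c(a, b, c, d) == "6")) {
      expect_false(is.na(k))
      expect_gt(k, 0)
      hits <- c(hits, thetaNames()[k])
    } else {
      expect_identical(k, 0L)
    }
  }
  # all 15 classes are reachable and both orientations map to one entry
  expect_setequal(unique(hits), thetaNames())
})

test_that("hairpin energy is a loop-length lookup with the minimum-loop guard", {
  p <- defaultEnergyParams()
  # GC closing a 4-loop: table value, no trainable term
  expect_equal(hairpinEnergy("GAAAAC", 1, 6, p), p@hairpinInit[4])
  expect_error(hairpinEnergy("GAAC", 1, 4, p), "below minimum")
  expect_error(hairpinEnergy("AAAAAA", 1, 6, p), "not pairable")
  # Jacobson-Stockmayer extrapolation beyond the table
  long <- paste0("G", strrep("A", 40), "C")
  expect_equal(hairpinEnergy(long, 1, 42, p),
               p@hairpinInit[30] + 1.75 / p@beta * log(40 / 30))
})

test_that("two-loop energy dispatches stack / bulge / internal correctly", {
  p <- gtParams()
  # 6C/GU stack resolves to the 6CUG entry (-1.79 kcal/mol)
  s <- "A6CAAAAGUU"                     # pairs (2,9)=6U, (3,8)=CG
  expect_equal(twoLoopEnergy(s, 2, 9, 3, 8, p), -1.79)
  # reversed orientation reads the same entry
  s2 <- "AUGAAAAC6U"                    # pairs (2,9)=U6, (3,8)=GC -> UG6C
  expect_equal(twoLoopEnergy(s2, 2, 9, 3, 8, p), theta(p)[["UG6C"]])
  # canonical GC/GC stack: Turner value, no theta dependence
  s3 <- "GGAAAACC"
  expect_equal(twoLoopEnergy(s3, 1, 8, 2, 7, p), -3.30)
  expect_equal(sum(twoLoopThetaGrad(s3, 1, 8, 2, 7, p)), 0)
  # bulge and internal loops by total length
  s4 <- "GAGAAAACC"                     # outer (1,9), inner (3,8): 1-nt bulge
  expect_equal(twoLoopEnergy(s4, 1, 9, 3, 8, p), p@bulgeInit[1])
  s5 <- "GAGAAAACAC"                    # outer (1,10), inner (3,8): 1x1 internal
  expect_equal(twoLoopEnergy(s5, 1, 10, 3, 8, p), p@internalInit[2])
  expect_error(twoLoopEnergy(s3, 2, 7, 1, 8, p), "i < h < l < j")
})

test_that("df2/dtheta is a one-hot indicator and f2 is linear in theta", {
  p <- gtParams()
  s <- "A6CAAAAGUU"
  g <- twoLoopThetaGrad(s, 2, 9, 3, 8, p)
  expect_equal(unname(g[["6CUG"]]), 1)
  expect_equal(sum(g), 1)
  # non-stack two-loop: all-zero indicator
  expect_equal(sum(twoLoopThetaGrad("GAGAAAACC", 1, 9, 3, 8, p)), 0)
  # finite-difference slope equals the indicator
  h <- 1e-6
  for (k in c("6CUG", "U66U")) {
    th <- theta(p); th[k] <- th[k] + h
    p2 <- defaultEnergyParams(th)
    slope <- (twoLoopEnergy(s, 2, 9, 3, 8, p2) -
              twoLoopEnergy(s, 2, 9, 3, 8, p)) / h
    expect_equal(slope, unname(g[k]), tolerance = 1e-6)
  }
})

test_that("reversal symmetry holds for canonical stack energies", {
  p <- defaultEnergyParams()
  al <- c("A", "C", "G", "U")
  set.seed(42)
  for (rep in 1:25) {
    a <- sample(al, 1); c <- sample(al, 1)
    b <- sample(al, 1); d <- sample(al, 1)
    if (!isPairable(a, c) || !isPairable(b, d)) next
    s1 <- paste0("A", a, b, "AAAA", d, c)   # pairs (2,9),(3,8)
    s2 <- paste0("A", d, c, "AAAA", a, b)   # the duplex read from the other strand
    expect_equal(twoLoopEnergy(s1, 2, 9, 3, 8, p),
                 twoLoopEnergy(s2, 2, 9, 3, 8, p))
  }
})

test_that("parameter TSV round-trips; missing and unknown names are handled", {
  p <- gtParams()
  tmp <- tempfile(fileext = ".tsv")
  writeParams(p, tmp)
  p2 <- readParams(tmp)
  expect_equal(theta(p2), theta(p))
  expect_equal(p2@f3, p@f3)
  # packaged GT fixture carries all 15 entries
  expect_length(gtTheta(), 15)
  expect_equal(unname(gtTheta()[c("6CUG", "UC6G", "6GUC", "UG6C")]),
               c(-1.79, -1.72, -1.56, -1.24))
  # missing entries fall back to init with a warning
  tab <- utils::read.delim(tmp)
  utils::write.table(tab[1:5, ], tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_warning(p3 <- readParams(tmp, init = -1), "missing")
  expect_equal(unname(theta(p3)[["U66U"]]), -1)
  # unknown parameter name is an error
  tab$name[1] <- "XXXX"
  utils::write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readParams(tmp), "unknown parameter")
})

test_that("ModRNA validates the alphabet and the length cap", {
  expect_silent(modRNA("acgu6"))
  expect_equal(as.character(modRNA("acgu6")), "ACGU6")
  expect_error(modRNA("ACGT"), "invalid characters")
  expect_error(modRNA(strrep("A", 201)), "longer than 200")
  expect_equal(length(modRNA("ACGU6")), 5L)
})
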