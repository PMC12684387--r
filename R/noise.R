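#' Multiplicative Gaussian noise on base-pairing probabilities
#'
#' Corrupts a base-pairing probability matrix entrywise:
#' P_new = max(0, P (1 + xi)) with xi ~ N(0, sigma^2), one independent
#' draw per unordered pair (i, j) applied symmetrically.  Entries made
#' negative by the noise are clipped to zero; no upper clipping at 1 is
#' applied, so recomputed marginals may exceed 1 (the L1 training loss
#' tolerates this).  Zero entries stay zero.  Marginals are recomputed
#' from the noisy matrix.
#'
#' @param x A [BppResult-class] or a symmetric probability matrix.
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Same type as `x`, with noisy P and recomputed mbpp.
#' @examples
#' res <- bpp("GGG6AAAAAUUCCC", defaultEnergyParams(gtTheta()))
#' noisy <- addBppNoise(res, sigma = 0.1, seed = 7)
#' @export
addBppNoise <- function(x, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  P <- if (is(x, "BppResult")) bppMatrix(x) else x
  n <- nrow(P)
  set.seed(seed)
  up <- upper.tri(P)
  xi <- stats::rnorm(sum(up), mean = 0, sd = sigma)
  Pn <- P
  Pn[up] <- pmax(0, P[up] * (1 + xi))
  Pn[lower.tri(Pn)] <- t(Pn)[lower.tri(Pn)]
  mb <- rowSums(Pn)
  if (is(x, "BppResult"))
    new("BppResult", seq = x@seq, P = Pn, mbpp = mb, Z = x@Z)
  else
    Pn
}
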