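# Shared fixtures: parameter sets and seeded random sequences.

gtParams <- function(...) defaultEnergyParams(gtTheta(), ...)

# random sequence over the extended alphabet; `modProb` controls how
# often m6A appears (draws assume set.seed was called by the test)
randomModSeq <- function(n, modProb = 0.1) {
  w <- c(A = (1 - modProb) / 4, C = (1 - modProb) / 4,
         G = (1 - modProb) / 4, U = (1 - modProb) / 4, `6` = modProb)
  paste(sample(names(w), n, replace = TRUE, prob = w), collapse = "")
}

# union over sequences of the theta classes realizable in each
bppActiveUnion <- function(seqs, params) {
  act <- setNames(rep(FALSE, 15), thetaNames())
  for (s in seqs) act <- act | bppGradients(s, params)$active
  act
}

# random canonical-only sequence
randomCanonSeq <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# sequence with nMods m6A at random A positions (redraws until enough A)
randomSeqWithMods <- function(n, nMods) {
  repeat {
    s <- strsplit(randomCanonSeq(n), "")[[1]]
    if (sum(s == "A") >= nMods) break
  }
  if (nMods > 0) s[sample(which(s == "A"), nMods)] <- "6"
  paste(s, collapse = "")
}
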