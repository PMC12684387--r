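#' RMSD between two base-pairing probability matrices
#'
#' 100 * sqrt(mean over i < j of (P_a - P_b)^2), in percent.  By
#' default every upper-triangle entry enters the mean (including
#' entries that are zero in both matrices); `entries = "nonzero"`
#' restricts to entries nonzero in at least one matrix.
#'
#' @param a,b [BppResult-class] objects or symmetric matrices of equal
#'   dimension.
#' @param entries "all" (default) or "nonzero".
#' @return RMSD in percent.
#' @export
bppRMSD <- function(a, b, entries = c("all", "nonzero")) {
  entries <- match.arg(entries)
  Pa <- if (is(a, "BppResult")) bppMatrix(a) else a
  Pb <- if (is(b, "BppResult")) bppMatrix(b) else b
  if (!identical(dim(Pa), dim(Pb))) stop("matrix dimensions differ")
  up <- upper.tri(Pa)
  da <- Pa[up]; db <- Pb[up]
  if (entries == "nonzero") {
    keep <- da != 0 | db != 0
    if (!any(keep)) return(0)
    da <- da[keep]; db <- db[keep]
  }
  100 * sqrt(mean((da - db)^2))
}

#' Recall and precision of predicted base pairs
#'
#' recall = |gt intersect pred| / |gt|;
#' precision = |gt intersect pred| / |pred|.  When both structures are
#' empty the pair is counted as a perfect match (1, 1).
#'
#' @param gt,pred [SecondaryStructure-class] objects or 2-column pair
#'   matrices, over sequences of equal length.
#' @return Named numeric c(recall, precision).
#' @export
recallPrecision <- function(gt, pred) {
  pg <- if (is(gt, "SecondaryStructure")) basePairs(gt) else gt
  pp <- if (is(pred, "SecondaryStructure")) basePairs(pred) else pred
  key <- function(m) if (nrow(m)) paste(m[, 1], m[, 2]) else character(0)
  kg <- key(pg); kp <- key(pp)
  if (!length(kg) && !length(kp))
    return(c(recall = 1, precision = 1))
  shared <- length(intersect(kg, kp))
  c(recall = if (length(kg)) shared / length(kg) else 1,
    precision = if (length(kp)) shared / length(kp) else 0)
}

#' Structure-level comparison of two parameter sets over a cohort
#'
#' Folds every sequence under both parameter sets and aggregates, per
#' sequence, the BPP-matrix RMSD and the recall/precision of the MFE
#' pair sets (ground-truth parameters define the reference pairs).
#'
#' @param seqs Character vector / list of sequences, or a design
#'   data.frame with a `seq` column.
#' @param paramsGt,paramsEst [EnergyParams-class] objects.
#' @param entries RMSD entry convention, see [bppRMSD()].
#' @return List with `summary` (mean and sd of each metric) and
#'   `perSequence` (data.frame).
#' @export
evaluateCohort <- function(seqs, paramsGt, paramsEst,
                           entries = c("all", "nonzero")) {
  entries <- match.arg(entries)
  if (is.data.frame(seqs)) seqs <- seqs$seq
  seqs <- as.list(seqs)
  stopifnot(length(seqs) >= 1L)
  per <- lapply(seq_along(seqs), function(q) {
    s <- seqs[[q]]
    rmsd <- bppRMSD(bpp(s, paramsGt), bpp(s, paramsEst), entries)
    rp <- recallPrecision(mfeFold(s, paramsGt), mfeFold(s, paramsEst))
    data.frame(index = q, rmsdPercent = rmsd,
               recall = rp[["recall"]], precision = rp[["precision"]])
  })
  per <- do.call(rbind, per)
  summ <- data.frame(
    metric = c("rmsdPercent", "recall", "precision"),
    mean = c(mean(per$rmsdPercent), mean(per$recall), mean(per$precision)),
    sd = c(stats::sd(per$rmsdPercent), stats::sd(per$recall),
           stats::sd(per$precision)))
  list(summary = summ, perSequence = per)
}
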