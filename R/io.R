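#' Read / write FASTA over the extended m6A alphabet
#'
#' FASTA parsing is delegated to Biostrings (BStringSet, since the '6'
#' letter is outside the standard RNA alphabet); every record is then
#' validated against \{A,C,G,U,6\} with lowercase normalized to
#' uppercase.  'T' or any other letter is rejected with the offending
#' record and column named.
#'
#' @param path File path.
#' @return `readModFasta`: named character vector of sequences.
#' @export
readModFasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  for (q in seq_along(seqs)) {
    bad <- regexpr("[^ACGU6]", seqs[q])
    if (bad > 0)
      stop(sprintf("record '%s': invalid character '%s' at column %d",
                   names(seqs)[q], substr(seqs[q], bad, bad), bad))
  }
  seqs
}

#' @rdname readModFasta
#' @param seqs Named character vector, list of sequences, or a design
#'   data.frame with columns id and seq.
#' @export
writeModFasta <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- stats::setNames(seqs$seq, seqs$id)
  seqs <- vapply(seqs, function(s) as.character(modRNA(s)), "")
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%d", seq_along(seqs))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read / write base-pairing probabilities as sparse TSV
#'
#' `i<TAB>j<TAB>prob`, 1-based with i < j; entries below 1e-9 are
#' omitted on write.  Marginals use `i<TAB>mbpp` with one row per base.
#'
#' @param x A [BppResult-class] or symmetric matrix.
#' @param path File path.
#' @return `readBppTsv` returns an n x n symmetric matrix.
#' @export
writeBppTsv <- function(x, path) {
  P <- if (is(x, "BppResult")) bppMatrix(x) else x
  up <- which(upper.tri(P) & P >= 1e-9, arr.ind = TRUE)
  tab <- data.frame(i = up[, 1], j = up[, 2], prob = P[up])
  tab <- tab[order(tab$i, tab$j), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeBppTsv
#' @param n Sequence length (matrix dimension).
#' @export
readBppTsv <- function(path, n) {
  tab <- utils::read.delim(path, header = TRUE)
  P <- matrix(0, n, n)
  P[cbind(tab$i, tab$j)] <- tab$prob
  P[cbind(tab$j, tab$i)] <- tab$prob
  P
}

#' @rdname writeBppTsv
#' @export
writeMbppTsv <- function(x, path) {
  v <- if (is(x, "BppResult")) mbpp(x) else as.numeric(x)
  utils::write.table(data.frame(i = seq_along(v), mbpp = v), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBppTsv
#' @export
readMbppTsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE)
  tab$mbpp[order(tab$i)]
}
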