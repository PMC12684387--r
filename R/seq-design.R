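# Designers for the synthetic training and evaluation sequences.  The
# workhorse is a 50-nt stem-loop: 10 random 5' bases, a 10-bp stem
# (bases 11-20 paired with 40-31), a 10-nt random loop (21-30) and 10
# random 3' bases.  One designated m6A-containing stack is placed at a
# chosen offset within the stem; the remaining stem positions are
# filled with random Watson-Crick pairs.

.CANONICAL_BASES <- c("A", "C", "G", "U")
.STEM_FILLERS <- list(c("G", "C"), c("C", "G"), c("A", "U"), c("U", "A"))

# longest-run check: does any complementary run of >= minRun exist
# outside the designed stem helix (pairs with p + q = 51)?
.hasCompetingRun <- function(s, minRun = 6L) {
  n <- length(s)
  p <- .pairMatrix()
  code <- match(s, .STACKGRAD_ALPHABET)
  run <- matrix(0L, n + 2L, n + 2L)
  for (i in n:1) for (j in n:1) {
    if (j - i < 2L) next
    if (p[code[i], code[j]]) run[i, j] <- run[i + 1L, j - 1L] + 1L
  }
  hits <- which(run[1:n, 1:n] >= minRun, arr.ind = TRUE)
  if (!nrow(hits)) return(FALSE)
  any(rowSums(hits) != 51L)
}

.designStemLoop <- function(stackName, position) {
  stopifnot(stackName %in% .THETA_NAMES, position >= 1L, position <= 9L)
  ch <- strsplit(stackName, "")[[1]]       # t1 t2 b1 b2
  for (try in seq_len(50L)) {
    s <- rep(NA_character_, 50L)
    s[c(1:10, 21:30, 41:50)] <- sample(.CANONICAL_BASES, 30L, replace = TRUE)
    # designated stack at stem offsets position, position + 1
    s[10L + position] <- ch[1]; s[11L + position] <- ch[2]
    s[41L - position] <- ch[3]; s[40L - position] <- ch[4]
    for (t in setdiff(1:10, c(position, position + 1L))) {
      f <- .STEM_FILLERS[[sample.int(4L, 1L)]]
      s[10L + t] <- f[1]; s[41L - t] <- f[2]
    }
    if (!.hasCompetingRun(s)) break
  }
  paste(s, collapse = "")
}

#' The minimum stem-loop design set (15 stacks x 9 positions)
#'
#' Generates one 50-nt stem-loop per (stack class, stem offset)
#' combination: 9 offsets shift the designated stack from stem pairs
#' 1-2 down to 9-10, and all 15 m6A stack classes are covered, giving
#' 135 sequences.  Flanks and loop are random canonical bases, redrawn
#' (up to 50 times) if they would create a competing complementary run
#' of 6+ bp against the stem.
#'
#' @param seed Integer seed (the set is deterministic given the seed).
#' @param stackNames Stack classes to include (default all 15).
#' @param positions Stem offsets to include (default 1:9).
#' @return data.frame with columns id, seq, stackName, position.
#' @examples
#' ds <- designMinimumSet(seed = 1)
#' nrow(ds)  # 135
#' @export
designMinimumSet <- function(seed = 1L, stackNames = thetaNames(),
                             positions = 1:9) {
  set.seed(seed)
  grid <- expand.grid(position = positions, stackName = stackNames,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$stackName, .THETA_NAMES), grid$position), ]
  seqs <- mapply(.designStemLoop, grid$stackName, grid$position)
  data.frame(id = sprintf("%s_p%d", grid$stackName, grid$position),
             seq = unname(seqs),
             stackName = grid$stackName,
             position = grid$position,
             row.names = NULL, stringsAsFactors = FALSE)
}

.randomCanonical <- function(length) {
  paste(sample(.CANONICAL_BASES, length, replace = TRUE), collapse = "")
}

#' Random sequences with a fixed number of m6A modifications
#'
#' Draws uniform random canonical sequences and converts `nMods`
#' adenosines (chosen uniformly among the A positions) to m6A;
#' sequences with fewer than `nMods` adenosines are redrawn.
#'
#' @param n Number of sequences.
#' @param length Sequence length (default 150).
#' @param nMods Number of A -> 6 substitutions (default 8).
#' @param seed Integer seed.
#' @return data.frame with columns id, seq.
#' @export
designRandomModified <- function(n, length = 150L, nMods = 8L, seed = 1L) {
  set.seed(seed)
  seqs <- character(n)
  for (q in seq_len(n)) {
    repeat {
      s <- strsplit(.randomCanonical(length), "")[[1]]
      aPos <- which(s == "A")
      if (length(aPos) >= nMods) break
    }
    if (nMods > 0L)
      s[sample(aPos, nMods)] <- "6"
    seqs[q] <- paste(s, collapse = "")
  }
  data.frame(id = sprintf("rnd%d_%dnt_%dmod", seq_len(n), length, nMods),
             seq = seqs, stringsAsFactors = FALSE)
}

#' Fully modified random sequences (every A becomes m6A)
#'
#' @inheritParams designRandomModified
#' @return data.frame with columns id, seq and canonical (the draw
#'   before substitution; replacing '6' by 'A' recovers it).
#' @export
designFullyModified <- function(n, length = 150L, seed = 1L) {
  set.seed(seed)
  canonical <- vapply(seq_len(n), function(q) .randomCanonical(length), "")
  data.frame(id = sprintf("full%d_%dnt", seq_len(n), length),
             seq = gsub("A", "6", canonical, fixed = TRUE),
             canonical = canonical, stringsAsFactors = FALSE)
}

#' Random evaluation cohorts (50 nt, 1/2/4/8 modifications)
#'
#' @inheritParams designRandomModified
#' @param nMods Number of modifications per sequence (1, 2, 4 or 8
#'   in the standard evaluation).
#' @return data.frame with columns id, seq.
#' @export
designEvalRandom <- function(n = 1000L, length = 50L, nMods = 8L,
                             seed = 1L) {
  designRandomModified(n, length = length, nMods = nMods, seed = seed)
}
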