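# Exhaustive enumeration oracle.  A deliberately independent, pure-R
# evaluation of the identical energy model: every pseudoknot-free
# structure of a short sequence is listed explicitly, scored by loop
# decomposition, and Z, P_ij, dZ/dtheta and the MFE are obtained by
# direct summation.  Used to validate the dynamic programs; guarded to
# N <= 18.

#' Enumerate all secondary structures of a short sequence
#'
#' Recursively lists every pseudoknot-free pair set respecting the
#' allowed-pair rule and the minimum hairpin loop, including the empty
#' structure, and scores each by the model's loop decomposition
#' (hairpin f1; two-loop f2 with canonical/theta stacks; multiloop
#' f3 + f4 (#unpaired) + f5 (#branches)).  Also counts, per structure,
#' how often each of the 15 m6A stack classes occurs.
#'
#' @inheritParams bpp
#' @return List of structures, each a list with `pairs` (matrix),
#'   `energy` (kcal/mol) and `nTheta` (named numeric(15) stack counts).
#' @export
enumerateStructures <- function(seq, params = defaultEnergyParams()) {
  seq <- modRNA(seq)
  n <- length(seq)
  if (n > 18L) stop("enumeration oracle is limited to N <= 18")
  s <- strsplit(as.character(seq), "")[[1]]
  code <- match(s, .STACKGRAD_ALPHABET)
  pmat <- .pairMatrix()
  minLoop <- params@minLoop
  memo <- new.env(parent = emptyenv())

  enum <- function(i, j) {
    if (j - i < minLoop + 1L) return(list(matrix(integer(0), 0, 2)))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- enum(i + 1L, j)                       # i unpaired
    for (l in (i + minLoop + 1L):j) {
      if (!pmat[code[i], code[l]]) next
      innerL <- enum(i + 1L, l - 1L)
      innerR <- if (l < j) enum(l + 1L, j) else list(matrix(integer(0), 0, 2))
      for (a in innerL) for (b in innerR)
        out[[length(out) + 1L]] <- rbind(c(i, l), a, b)
    }
    memo[[key]] <- out
    out
  }

  structs <- enum(1L, n)
  lapply(structs, function(pr) {
    sc <- .oracleScore(s, pr, params)
    list(pairs = pr[order(pr[, 1]), , drop = FALSE],
         energy = sc$energy, nTheta = sc$nTheta)
  })
}

# loop-decomposition score of one structure (independent of the DP)
.oracleScore <- function(s, pairs, params) {
  nTheta <- stats::setNames(numeric(15), .THETA_NAMES)
  if (!nrow(pairs))
    return(list(energy = 0, nTheta = nTheta))
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  np <- nrow(pairs)
  # parent of each pair = tightest enclosing pair
  parent <- integer(np)
  for (q in seq_len(np)) {
    i <- pairs[q, 1]; j <- pairs[q, 2]
    enc <- which(pairs[, 1] < i & pairs[, 2] > j)
    parent[q] <- if (length(enc)) enc[which.max(pairs[enc, 1])] else 0L
  }
  energy <- 0
  pt <- function(x, y) match(paste0(x, y), .PAIR_TYPES)
  for (q in seq_len(np)) {
    i <- pairs[q, 1]; j <- pairs[q, 2]
    kids <- which(parent == q)
    if (length(kids) == 0L) {
      energy <- energy + .loopExtrap(params@hairpinInit, j - i - 1L,
                                     params@beta)
    } else if (length(kids) == 1L) {
      h <- pairs[kids, 1]; l <- pairs[kids, 2]
      if (h == i + 1L && l == j - 1L) {
        k <- .stackClass(s[i], s[h], s[j], s[l])
        if (k > 0L) {
          energy <- energy + unname(params@theta[k])
          nTheta[k] <- nTheta[k] + 1
        } else {
          energy <- energy + params@canonicalStacks[pt(s[i], s[j]),
                                                    pt(s[l], s[h])]
        }
      } else {
        ll <- h - i - 1L; rl <- j - l - 1L
        tab <- if (ll == 0L || rl == 0L) params@bulgeInit
               else params@internalInit
        energy <- energy + .loopExtrap(tab, ll + rl, params@beta)
      }
    } else {
      unpaired <- (j - i - 1L) -
        sum(pairs[kids, 2] - pairs[kids, 1] + 1L)
      energy <- energy + params@f3 + params@f5 * length(kids) +
        params@f4 * unpaired
    }
  }
  list(energy = energy, nTheta = nTheta)
}

#' Oracle quantities by direct summation over the ensemble
#'
#' `oracleZ` returns sum_s exp(-beta E(s)); `oracleBpp` the pair
#' probability matrix sum_{s containing (i,j)} exp(-beta E) / Z and its
#' marginals; `oracleGradZ` the vector dZ/dtheta_k =
#' sum_s (-beta n_k(s)) exp(-beta E(s)); `oracleMfe` the minimum
#' energy (0 for the open chain) and one minimizing pair set.
#'
#' @inheritParams bpp
#' @param ensemble Optionally a precomputed [enumerateStructures()]
#'   result, to avoid re-enumeration.
#' @return See details above.
#' @export
oracleZ <- function(seq, params = defaultEnergyParams(), ensemble = NULL) {
  if (is.null(ensemble)) ensemble <- enumerateStructures(seq, params)
  sum(vapply(ensemble, function(st) exp(-params@beta * st$energy), 0))
}

#' @rdname oracleZ
#' @export
oracleBpp <- function(seq, params = defaultEnergyParams(), ensemble = NULL) {
  seq <- modRNA(seq)
  if (is.null(ensemble)) ensemble <- enumerateStructures(seq, params)
  n <- length(seq)
  w <- vapply(ensemble, function(st) exp(-params@beta * st$energy), 0)
  Z <- sum(w)
  P <- matrix(0, n, n)
  for (q in seq_along(ensemble)) {
    pr <- ensemble[[q]]$pairs
    if (nrow(pr))
      P[pr] <- P[pr] + w[q]
  }
  P <- P / Z
  P <- P + t(P)
  list(P = P, mbpp = rowSums(P), Z = Z)
}

#' @rdname oracleZ
#' @export
oracleGradZ <- function(seq, params = defaultEnergyParams(),
                        ensemble = NULL) {
  if (is.null(ensemble)) ensemble <- enumerateStructures(seq, params)
  g <- stats::setNames(numeric(15), .THETA_NAMES)
  for (st in ensemble)
    g <- g + (-params@beta) * st$nTheta * exp(-params@beta * st$energy)
  g
}

#' @rdname oracleZ
#' @export
oracleMfe <- function(seq, params = defaultEnergyParams(),
                      ensemble = NULL) {
  if (is.null(ensemble)) ensemble <- enumerateStructures(seq, params)
  en <- vapply(ensemble, function(st) st$energy, 0)
  best <- which.min(en)
  if (en[best] >= 0)
    return(list(energy = 0, pairs = matrix(integer(0), 0, 2)))
  list(energy = en[best], pairs = ensemble[[best]]$pairs)
}

#' Count secondary structures by dynamic programming
#'
#' Nussinov-style counting recursion (Boltzmann weights set to 1),
#' used as an independent check on the enumeration itself.
#'
#' @inheritParams bpp
#' @param minLoop Minimum hairpin loop size.
#' @return Number of structures, including the empty one.
#' @export
countStructures <- function(seq, minLoop = 3L) {
  seq <- modRNA(seq)
  n <- length(seq)
  code <- .encodeSeq(seq)
  pmat <- .pairMatrix()
  C <- matrix(1, n + 2L, n + 2L)   # empty interval -> 1
  if (n < minLoop + 2L) return(1)
  for (d in seq(minLoop + 1L, n - 1L)) {
    for (i in seq_len(n - d)) {
      j <- i + d
      acc <- C[i + 1L, j]
      for (l in (i + minLoop + 1L):j) {
        if (!pmat[code[i], code[l]]) next
        right <- if (l < j) C[l + 1L, j] else 1
        acc <- acc + C[i + 1L, l - 1L] * right
      }
      C[i, j] <- acc
    }
  }
  C[1L, n]
}
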