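#' Minimum free energy structure (Zuker algorithm)
#'
#' Zuker-style MFE folding under exactly the same energy model as the
#' partition function: hairpin f1, two-loop f2 (canonical or m6A
#' stack, bulge, internal loop) and linear multiloops
#' f3 + f4 (#unpaired) + f5 (#branches).  The traceback is
#' deterministic; on exact ties it prefers hairpin over two-loop over
#' multiloop closures and then the smallest (h, l).
#'
#' @inheritParams bpp
#' @return A [SecondaryStructure-class]; the open chain (energy 0) when
#'   no structure has negative energy.
#' @examples
#' mfeFold("GGG6AAAAAUUCCC", defaultEnergyParams(gtTheta()))
#' @export
mfeFold <- function(seq, params = defaultEnergyParams()) {
  seq <- modRNA(seq)
  out <- cpp_mfe(.encodeSeq(seq), .params2cpp(params))
  pairs <- out$pairs
  if (nrow(pairs)) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  new("SecondaryStructure", pairs = pairs,
      dotBracket = .pairs2db(pairs, length(seq)),
      energy = out$energy, length = length(seq))
}

.pairs2db <- function(pairs, n) {
  v <- rep(".", n)
  if (nrow(pairs)) {
    v[pairs[, 1]] <- "("
    v[pairs[, 2]] <- ")"
  }
  paste(v, collapse = "")
}

#' Parse a dot-bracket string
#'
#' @param db Dot-bracket string over ".()".
#' @return A [SecondaryStructure-class] with energy NA.
#' @export
parseDotBracket <- function(db) {
  v <- strsplit(db, "")[[1]]
  if (!all(v %in% c(".", "(", ")"))) stop("dot-bracket must use '.()'")
  stack <- integer(0)
  pairs <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  for (p in seq_along(v)) {
    if (v[p] == "(") stack <- c(stack, p)
    else if (v[p] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket at column ", p)
      pairs <- rbind(pairs, c(stack[length(stack)], p))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unclosed '('")
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  new("SecondaryStructure", pairs = pairs, dotBracket = db,
      energy = NA_real_, length = length(v))
}

#' @rdname SecondaryStructure-accessors
#' @name SecondaryStructure-accessors
#' @title Accessors for SecondaryStructure
#' @param x A [SecondaryStructure-class] object.
#' @return `basePairs`: integer matrix (i, j); `dotBracket`: string;
#'   `foldEnergy`: scalar kcal/mol.
NULL

#' @rdname SecondaryStructure-accessors
#' @export
setMethod("basePairs", "SecondaryStructure", function(x) x@pairs)

#' @rdname SecondaryStructure-accessors
#' @export
setMethod("dotBracket", "SecondaryStructure", function(x) x@dotBracket)

#' @rdname SecondaryStructure-accessors
#' @export
setMethod("foldEnergy", "SecondaryStructure", function(x) x@energy)

#' @describeIn SecondaryStructure-accessors Sequence length.
#' @export
setMethod("length", "SecondaryStructure", function(x) x@length)

setMethod("show", "SecondaryStructure", function(object) {
  cat(sprintf("SecondaryStructure: %d nt, %d pairs, %.2f kcal/mol\n  %s\n",
              object@length, nrow(object@pairs), object@energy,
              object@dotBracket))
})
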