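#' @import methods
NULL

#' RNA sequence over the extended m6A alphabet
#'
#' A validated RNA sequence over \{A, C, G, U, 6\}, where '6' encodes
#' N6-methyladenosine (m6A).  All coordinates used by the package are
#' 1-based.  Sequences longer than 200 nt are rejected: the partition
#' function is computed in raw floating point without rescaling, which
#' is safe only for short sequences.
#'
#' @slot seq Single uppercase character string over \{A,C,G,U,6\}.
#' @export
setClass("ModRNA", representation(seq = "character"))

setValidity("ModRNA", function(object) {
  s <- object@seq
  if (length(s) != 1L || is.na(s)) return("'seq' must be a single string")
  if (nchar(s) < 1L) return("empty sequence")
  if (nchar(s) > 200L)
    return("sequences longer than 200 nt are not supported (no rescaling)")
  bad <- regmatches(s, gregexpr("[^ACGU6]", s))[[1]]
  if (length(bad))
    return(sprintf("invalid characters (first at column %d): '%s'",
                   regexpr("[^ACGU6]", s), bad[1]))
  TRUE
})

#' Nearest-neighbor energy parameter set
#'
#' Holds every energy term of the folding model: the canonical Turner
#' stacking table, the 15 trainable m6A stacking parameters theta, loop
#' initiation tables by length, the linear multiloop constants f3
#' (closing), f4 (per unpaired base) and f5 (per branch), and the
#' inverse temperature beta = 1/RT.  All energies are kcal/mol at 37 C.
#'
#' @slot theta Named numeric(15), m6A stack free energies (kcal/mol).
#' @slot canonicalStacks 6x6 numeric matrix over canonical pair types.
#' @slot hairpinInit,bulgeInit,internalInit Numeric(30) loop initiation
#'   free energies by loop size; extrapolated beyond 30 nt by the
#'   Jacobson-Stockmayer term 1.75 RT log(n/30).
#' @slot f3,f4,f5 Multiloop constants (kcal/mol); base-type independent,
#'   so their derivatives with respect to theta vanish.
#' @slot beta Inverse temperature 1/RT (mol/kcal); default 37 C.
#' @slot minLoop Minimum hairpin loop size (unpaired bases), default 3.
#' @export
setClass("EnergyParams", representation(
  theta = "numeric",
  canonicalStacks = "matrix",
  hairpinInit = "numeric",
  bulgeInit = "numeric",
  internalInit = "numeric",
  f3 = "numeric",
  f4 = "numeric",
  f5 = "numeric",
  beta = "numeric",
  minLoop = "integer"))

setValidity("EnergyParams", function(object) {
  if (length(object@theta) != 15L ||
      !identical(sort(names(object@theta)), sort(.THETA_NAMES)))
    return("'theta' must hold exactly the 15 named m6A stack entries")
  if (!identical(dim(object@canonicalStacks), c(6L, 6L)))
    return("'canonicalStacks' must be a 6x6 matrix")
  for (nm in c("hairpinInit", "bulgeInit", "internalInit"))
    if (length(slot(object, nm)) != 30L)
      return(sprintf("'%s' must have length 30", nm))
  if (length(object@beta) != 1L || object@beta <= 0)
    return("'beta' must be a single positive number")
  if (object@minLoop < 0L) return("'minLoop' must be >= 0")
  TRUE
})

#' Base-pairing probability result
#'
#' Result of the McCaskill inside-outside computation: the symmetric
#' base-pairing probability matrix P, its row marginals
#' (marginalized base-pairing probabilities, MBPP_i = sum_j P_ij), and
#' the total partition function Z_{1,N}.
#'
#' @slot seq The folded [ModRNA-class] sequence.
#' @slot P N x N symmetric numeric matrix of pair probabilities.
#' @slot mbpp Numeric(N), marginal probability that base i is paired.
#' @slot Z Total partition function (dimensionless, >= 1).
#' @export
setClass("BppResult", representation(
  seq = "ModRNA", P = "matrix", mbpp = "numeric", Z = "numeric"))

#' RNA secondary structure
#'
#' A pseudoknot-free secondary structure: a set of non-crossing base
#' pairs with its free energy under the model, plus the dot-bracket
#' rendering.
#'
#' @slot pairs Integer matrix with columns i, j (i < j).
#' @slot dotBracket Dot-bracket string.
#' @slot energy Free energy (kcal/mol); 0 for the open chain.
#' @slot length Sequence length.
#' @export
setClass("SecondaryStructure", representation(
  pairs = "matrix", dotBracket = "character", energy = "numeric",
  length = "integer"))

#' Gradient-descent training result
#'
#' @slot theta Named numeric(15): fitted parameters (kcal/mol).
#' @slot lossHistory data.frame with columns update, epoch, seqIndex,
#'   loss (one row per parameter update, loss evaluated pre-update).
#' @slot thetaTrajectory Numeric matrix (updates x 15) of parameter
#'   values after each update, or a 0-row matrix when tracing is off.
#' @slot epochs,updateCount Integers.
#' @slot learningRate Learning rate used (kcal/mol per unit gradient).
#' @export
setClass("TrainResult", representation(
  theta = "numeric", lossHistory = "data.frame",
  thetaTrajectory = "matrix", epochs = "integer",
  updateCount = "integer", learningRate = "numeric"))
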