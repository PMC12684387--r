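#' Base-pairing probabilities by the McCaskill algorithm
#'
#' Computes the inside partition functions (Z, Z1, Zb, Zm, Zm1), the
#' outside function Wb, and from them the base-pairing probability
#' matrix P_ij = Zb_ij Wb_ij / Z_1N together with its marginals
#' MBPP_i = sum_j P_ij.  The ensemble is the set of pseudoknot-free
#' structures over the allowed pairs (AU, UA, GC, CG, GU, UG, 6U, U6)
#' with a minimum hairpin loop of `minLoop` bases; multiloops follow
#' the linear model f3 + f4 (#unpaired) + f5 (#branches).
#'
#' Everything is computed in raw floating point without rescaling
#' (safe at the <= 200 nt lengths this package accepts); complexity is
#' O(N^4) from the unrestricted two-loop double sum.
#'
#' @param seq Sequence ([ModRNA-class] or string over \{A,C,G,U,6\}).
#' @param params [EnergyParams-class] (default [defaultEnergyParams()]).
#' @return A [BppResult-class] object.
#' @examples
#' res <- bpp("GGG6AAAAAUUCCC", defaultEnergyParams(gtTheta()))
#' mbpp(res)
#' @export
bpp <- function(seq, params = defaultEnergyParams()) {
  seq <- modRNA(seq)
  out <- cpp_fold(.encodeSeq(seq), .params2cpp(params), FALSE)
  new("BppResult", seq = seq, P = out$P, mbpp = as.numeric(out$mbpp),
      Z = out$Z)
}

#' Inside/outside dynamic-programming tables
#'
#' Low-level access to the filled DP tables, mainly for validation:
#' returns the full N x N matrices for Z, Z1, Zb, Zm, Zm1 and Wb along
#' with Z_1N, P and mbpp.
#'
#' @inheritParams bpp
#' @return A list with elements `Z` (scalar Z_1N), `P`, `mbpp` and
#'   `tables` (list of six matrices).
#' @export
insideOutside <- function(seq, params = defaultEnergyParams()) {
  seq <- modRNA(seq)
  cpp_fold(.encodeSeq(seq), .params2cpp(params), TRUE)
}

#' @rdname BppResult-accessors
#' @name BppResult-accessors
#' @title Accessors for BppResult
#' @param x A [BppResult-class] object.
#' @return `bppMatrix`: the symmetric probability matrix; `mbpp`: the
#'   marginal vector; `partitionFunction`: the scalar Z_1N.
NULL

#' @rdname BppResult-accessors
#' @export
setMethod("bppMatrix", "BppResult", function(x) x@P)

#' @rdname BppResult-accessors
#' @export
setMethod("mbpp", "BppResult", function(x) x@mbpp)

#' @rdname BppResult-accessors
#' @export
setMethod("partitionFunction", "BppResult", function(x) x@Z)

setMethod("show", "BppResult", function(object) {
  n <- length(object@mbpp)
  cat(sprintf("BppResult: %d nt, Z = %.6g, %d pairs with P > 0.01\n",
              n, object@Z, sum(object@P[upper.tri(object@P)] > 0.01)))
})
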