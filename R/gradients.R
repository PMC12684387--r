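#' Derivatives of base-pairing probabilities with respect to theta
#'
#' Computes, by differentiated dynamic programming, the derivative of
#' every base-pairing probability P_ij (and of the marginals MBPP_i)
#' with respect to each trainable m6A stacking parameter.  The forward
#' inside/outside tables are filled once and reused; a dedicated
#' derivative table set is filled per parameter by product-rule
#' expansion of each recursion.  Because theta enters the model only
#' through the stack case of f2, the derivative seeds are the 0/1
#' stack-class indicators ([twoLoopThetaGrad()]); f1, f3, f4, f5 are
#' base-type independent constants with zero derivative.
#'
#' Parameters whose stack class cannot occur anywhere in the sequence
#' have identically zero derivative tables and are skipped.
#'
#' @inheritParams bpp
#' @param which Integer or character vector of theta entries to
#'   differentiate; default all classes realizable in the sequence.
#' @param withTables Return the full derivative DP tables as well.
#' @return A list with `active` (logical(15)) and `perTheta`, a list of
#'   15 slots (NULL where inactive) each holding `dP` (N x N matrix),
#'   `dmbpp` (numeric(N)), `dZ` (scalar dZ_1N) and, if requested,
#'   `tables`.
#' @export
bppGradients <- function(seq, params = defaultEnergyParams(),
                         which = NULL, withTables = FALSE) {
  seq <- modRNA(seq)
  if (is.character(which)) which <- match(which, .THETA_NAMES)
  w <- if (is.null(which)) integer(0) else as.integer(which)
  out <- cpp_grad(.encodeSeq(seq), .params2cpp(params), w, withTables)
  names(out$perTheta) <- .THETA_NAMES
  names(out$active) <- .THETA_NAMES
  out[c("perTheta", "active")]
}

#' Marginal-probability gradients
#'
#' Convenience wrapper returning d(MBPP_i)/d(theta_k) as a 15 x N
#' matrix (zero rows for parameters absent from the sequence).
#'
#' @inheritParams bppGradients
#' @return Numeric matrix, rows named by [thetaNames()].
#' @export
mbppGradients <- function(seq, params = defaultEnergyParams()) {
  g <- bppGradients(seq, params)
  n <- length(modRNA(seq))
  out <- matrix(0, 15, n, dimnames = list(.THETA_NAMES, NULL))
  for (k in seq_len(15))
    if (!is.null(g$perTheta[[k]])) out[k, ] <- g$perTheta[[k]]$dmbpp
  out
}
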