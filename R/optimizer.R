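#' L1 loss between marginalized base-pairing probability vectors
#'
#' loss = sum_i |gt_i - est_i|.  The marginals (rather than the full
#' matrix) are compared because probing-style measurements report how
#' exposed a base is, not whom it pairs with.
#'
#' @param mbppGt,mbppEst Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
lossL1 <- function(mbppGt, mbppEst) {
  if (length(mbppGt) != length(mbppEst))
    stop("mbpp vectors differ in length")
  sum(abs(mbppGt - mbppEst))
}

#' Gradient of the L1 loss with respect to theta
#'
#' d loss / d theta_k = sum_i sign(MBPP_i - MBPP_i^GT) d MBPP_i / d
#' theta_k, with the subgradient convention sign(0) = 0.
#'
#' @inheritParams bpp
#' @param mbppGt Ground-truth marginal vector (length N).
#' @return List with `loss` (scalar) and `grad` (named numeric(15)).
#' @export
lossGradient <- function(seq, params, mbppGt) {
  seq <- modRNA(seq)
  stopifnot(length(mbppGt) == length(seq))
  out <- cpp_loss_grad(.encodeSeq(seq), .params2cpp(params),
                       as.numeric(mbppGt))
  list(loss = out$loss,
       grad = stats::setNames(as.numeric(out$grad), .THETA_NAMES))
}

#' Fit m6A stacking parameters by per-sequence gradient descent
#'
#' Plain SGD: one parameter update per training sequence per epoch, in
#' a fixed order (optionally shuffled once with a seed), minimizing the
#' L1 loss on marginalized base-pairing probabilities.  Each update
#' recomputes the forward inside/outside pass and the derivative DP for
#' every parameter class realizable in that sequence; parameters whose
#' stack never occurs receive exactly zero gradient and remain at their
#' initial value.  No momentum, weight decay or schedule is applied.
#'
#' The descent is carried out on theta expressed in `energyUnit`
#' kcal/mol steps -- by default centi-kcal/mol, the integer energy
#' quantum of thermodynamic folding engines.  By the chain rule the
#' update in kcal/mol is theta <- theta - lr * energyUnit^2 *
#' dloss/dtheta.  With the default unit, lr = 50.0 gives kcal-scale
#' steps of a few 1e-3 per unit gradient, the regime in which the
#' L1 objective descends smoothly to the reference parameters.
#'
#' @param seqs List of sequences ([ModRNA-class] or strings).
#' @param mbppGt List of ground-truth marginal vectors, parallel to
#'   `seqs` (possibly noise-corrupted).
#' @param params [EnergyParams-class] supplying all non-trainable
#'   energies.
#' @param epochs Number of passes over the training set.
#' @param lr Learning rate (default 50.0), in `energyUnit` steps per
#'   unit loss gradient.
#' @param initTheta Initial value for all 15 parameters (default
#'   -1.00 kcal/mol) or a named numeric(15).
#' @param energyUnit Internal energy quantum of the descent, kcal/mol
#'   (default 0.01).
#' @param shuffle Shuffle the sequence order once before training.
#' @param seed Seed used when `shuffle = TRUE`.
#' @param trace Record the full theta trajectory (updates x 15).
#' @param guard Abort if any |theta| exceeds this bound (kcal/mol).
#' @return A [TrainResult-class] object.
#' @examples
#' \donttest{
#' gt <- defaultEnergyParams(gtTheta())
#' ds <- designMinimumSet(seed = 1)[1:9, ]
#' mb <- lapply(ds$seq, function(s) mbpp(bpp(s, gt)))
#' fit <- trainParams(ds$seq, mb, gt, epochs = 10)
#' theta(fit)[["6CUG"]]
#' }
#' @export
trainParams <- function(seqs, mbppGt, params = defaultEnergyParams(),
                        epochs = 300L, lr = 50.0, initTheta = -1.00,
                        energyUnit = 0.01, shuffle = FALSE, seed = 1L,
                        trace = FALSE, guard = 50.0) {
  stopifnot(length(seqs) >= 1L, length(seqs) == length(mbppGt))
  seqs <- lapply(seqs, modRNA)
  for (q in seq_along(seqs))
    if (length(mbppGt[[q]]) != length(seqs[[q]]))
      stop("mbppGt[[", q, "]] length does not match its sequence")
  if (length(initTheta) == 1L)
    initTheta <- stats::setNames(rep(initTheta, 15L), .THETA_NAMES)
  initTheta <- initTheta[.THETA_NAMES]
  ord <- seq_along(seqs)
  if (shuffle) {
    set.seed(seed)
    ord <- sample(ord)
  }
  enc <- lapply(seqs[ord], .encodeSeq)
  gts <- lapply(mbppGt[ord], as.numeric)
  out <- cpp_train(enc, gts, .params2cpp(params), unname(initTheta),
                   as.integer(epochs), lr * energyUnit^2, guard, trace)
  nUpd <- length(out$loss)
  traj <- out$traj
  if (trace) colnames(traj) <- .THETA_NAMES
  new("TrainResult",
      theta = stats::setNames(as.numeric(out$theta), .THETA_NAMES),
      lossHistory = data.frame(update = seq_len(nUpd),
                               epoch = out$epoch,
                               seqIndex = ord[out$seqIndex],
                               loss = out$loss),
      thetaTrajectory = traj,
      epochs = as.integer(epochs),
      updateCount = nUpd,
      learningRate = lr)
}

#' One gradient-descent step
#'
#' Applies theta <- theta - lr * dloss/dtheta for a single training
#' example and returns the updated parameters with the pre-update loss.
#'
#' @inheritParams lossGradient
#' @param lr Learning rate, in `energyUnit` steps per unit gradient.
#' @param energyUnit Internal energy quantum (kcal/mol).
#' @return List with `params` (updated [EnergyParams-class]) and
#'   `loss`.
#' @export
sgdStep <- function(seq, params, mbppGt, lr = 50.0, energyUnit = 0.01) {
  g <- lossGradient(seq, params, mbppGt)
  theta(params) <- theta(params) - lr * energyUnit^2 * g$grad
  list(params = params, loss = g$loss)
}

#' @rdname theta
#' @export
setMethod("theta", "TrainResult", function(x) x@theta)

#' @rdname TrainResult-accessors
#' @name TrainResult-accessors
#' @title Accessors for TrainResult
#' @param x A [TrainResult-class] object.
#' @return `lossHistory`: data.frame of per-update losses;
#'   `updateCount`: integer; `thetaTrajectory`: matrix.
NULL

#' @rdname TrainResult-accessors
#' @export
setMethod("lossHistory", "TrainResult", function(x) x@lossHistory)

#' @rdname TrainResult-accessors
#' @export
setMethod("updateCount", "TrainResult", function(x) x@updateCount)

#' @rdname TrainResult-accessors
#' @export
setMethod("thetaTrajectory", "TrainResult", function(x) x@thetaTrajectory)

setMethod("show", "TrainResult", function(object) {
  cat(sprintf("TrainResult: %d updates (%d epochs), lr = %.1f\n",
              object@updateCount, object@epochs, object@learningRate))
  cat(sprintf("  final loss %.4g (initial %.4g)\n",
              utils::tail(object@lossHistory$loss, 1),
              object@lossHistory$loss[1]))
  print(round(object@theta, 3))
})
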