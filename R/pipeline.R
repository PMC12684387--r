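#' End-to-end parameter-recovery pipeline
#'
#' Orchestrates the whole inverse-estimation experiment: design the
#' stem-loop training set, compute ground-truth base-pairing
#' probabilities under the reference parameters, optionally corrupt
#' them with multiplicative Gaussian noise, train the 15 m6A stack
#' parameters by SGD, and (optionally) evaluate the fitted parameters
#' on an independent random cohort.  Every artifact is written to
#' `outDir`: sequences.fa, design.tsv, params_gt.tsv, params_est.tsv,
#' loss.csv, config.dcf and (if evaluated) eval.tsv.
#'
#' @param outDir Output directory (created if missing).
#' @param stackNames Stack classes to design for (default all 15).
#' @param positions Stem offsets (default 1:9).
#' @param epochs,lr,initTheta Training settings (defaults 300, 50.0,
#'   -1.00).
#' @param sigma Noise standard deviation on the GT probabilities
#'   (default 0: noiseless).
#' @param seed Integer seed controlling design and noise.
#' @param paramsGt Reference parameters (default Turner canonical +
#'   [gtTheta()] m6A stacks).
#' @param evalCohort Number of random 50-nt/8-mod evaluation
#'   sequences (0 = skip evaluation).
#' @param trace Record the theta trajectory.
#' @return List with `fit` ([TrainResult-class]), `design`
#'   (data.frame), `eval` (or NULL) and `outDir`.
#' @export
runPipeline <- function(outDir, stackNames = thetaNames(),
                        positions = 1:9, epochs = 300L, lr = 50.0,
                        initTheta = -1.00, sigma = 0, seed = 1L,
                        paramsGt = defaultEnergyParams(gtTheta()),
                        evalCohort = 0L, trace = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfg <- data.frame(epochs = epochs, lr = lr, initTheta = initTheta,
                    sigma = sigma, seed = seed,
                    nStacks = length(stackNames),
                    nPositions = length(positions),
                    evalCohort = evalCohort, formatVersion = 1L)
  write.dcf(cfg, file.path(outDir, "config.dcf"))

  design <- designMinimumSet(seed = seed, stackNames = stackNames,
                             positions = positions)
  utils::write.table(design[c("id", "stackName", "position")],
                     file.path(outDir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeModFasta(design, file.path(outDir, "sequences.fa"))
  writeParams(paramsGt, file.path(outDir, "params_gt.tsv"))

  message(sprintf("computing GT base-pairing probabilities (%d sequences)",
                  nrow(design)))
  gtBpp <- lapply(design$seq, bpp, params = paramsGt)
  if (sigma > 0)
    gtBpp <- lapply(seq_along(gtBpp), function(q)
      addBppNoise(gtBpp[[q]], sigma, seed = seed + q))
  gtMbpp <- lapply(gtBpp, mbpp)

  message(sprintf("training: %d sequences x %d epochs = %d updates",
                  nrow(design), epochs, nrow(design) * epochs))
  fit <- trainParams(design$seq, gtMbpp, paramsGt, epochs = epochs,
                     lr = lr, initTheta = initTheta, trace = trace)
  est <- paramsGt
  theta(est) <- theta(fit)
  writeParams(est, file.path(outDir, "params_est.tsv"))
  utils::write.csv(lossHistory(fit), file.path(outDir, "loss.csv"),
                   row.names = FALSE)

  evalRes <- NULL
  if (evalCohort > 0L) {
    cohort <- designEvalRandom(evalCohort, length = 50L, nMods = 8L,
                               seed = seed + 10000L)
    evalRes <- evaluateCohort(cohort, paramsGt, est)
    utils::write.table(evalRes$perSequence,
                       file.path(outDir, "eval.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(fit = fit, design = design, eval = evalRes, outDir = outDir)
}

#' Read a pipeline configuration file
#'
#' @param path Path to a config.dcf written by [runPipeline()].
#' @return data.frame of settings.
#' @export
readRunConfig <- function(path) {
  as.data.frame(read.dcf(path), stringsAsFactors = FALSE)
}
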