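Package: stackGrad
Title: Inverse Estimation of RNA Stacking Energy Parameters from
    Base-Pairing Probabilities
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates nearest-neighbor stacking energy parameters of
    modified nucleotides (N6-methyladenosine, m6A) from base-pairing
    probabilities by solving an inverse folding problem. Base-pairing
    probabilities are computed with the McCaskill inside-outside
    partition function over an extended alphabet {A,C,G,U,6}, their
    analytic derivatives with respect to the trainable stacking
    parameters are obtained by differentiated dynamic programming, and
    the parameters are fitted by gradient descent on an L1 loss over
    marginalized base-pairing probabilities. Includes Zuker-style
    minimum free energy folding under the same energy model, sequence
    designers for stem-loop training sets, a multiplicative Gaussian
    noise model for probing-like data, structure-level evaluation
    (RMSD, recall, precision), and an exhaustive enumeration oracle for
    validating the dynamic programs on short sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: StructuralPrediction, Software, RNASeq
RoxygenNote: 7.3.3
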