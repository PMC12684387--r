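# Embedded nearest-neighbor constants (Turner 2004, 37 C, kcal/mol).
# Only loop-length initiations, canonical stacking and the linear
# multiloop model are used: terminal mismatches, AU/GU end penalties,
# dangles and special hairpins are deliberately not part of this model
# (the forward model and the inverse problem share one self-consistent
# energy function).

#' @keywords internal
.STACKGRAD_ALPHABET <- c("A", "C", "G", "U", "6")

# canonical pair type order used by the stacking table
.PAIR_TYPES <- c("CG", "GC", "GU", "UG", "AU", "UA")

# E(outer pair (i,j), inner pair (l,h)): outer pair indexes rows, the
# inner pair read 3'->5' (i.e. (s_l, s_h)) indexes columns.
.CANONICAL_STACKS <- matrix(c(
  -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,
  -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,
  -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,
  -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,
  -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,
  -2.10, -2.40, -1.30, -1.00, -0.90, -1.30),
  nrow = 6, byrow = TRUE,
  dimnames = list(.PAIR_TYPES, .PAIR_TYPES))

# loop initiation free energies by loop size 1..30 (Inf = forbidden)
.HAIRPIN_INIT <- c(Inf, Inf, 5.40, 5.60, 5.70, 5.40, 6.00, 5.50, 6.40,
                   6.50, 6.60, 6.70, 6.80, 6.90, 6.90, 7.00, 7.10, 7.10,
                   7.20, 7.20, 7.30, 7.30, 7.40, 7.40, 7.50, 7.50, 7.50,
                   7.60, 7.60, 7.70)
.BULGE_INIT <- c(3.80, 2.80, 3.20, 3.60, 4.00, 4.40, 4.60, 4.70, 4.80,
                 4.90, 5.00, 5.10, 5.20, 5.30, 5.40, 5.40, 5.50, 5.50,
                 5.60, 5.70, 5.70, 5.80, 5.80, 5.80, 5.90, 5.90, 6.00,
                 6.00, 6.00, 6.10)
.INTERNAL_INIT <- c(Inf, 1.00, 1.00, 1.10, 2.00, 2.00, 2.10, 2.30, 2.40,
                    2.50, 2.60, 2.70, 2.80, 2.90, 2.90, 3.00, 3.10, 3.10,
                    3.20, 3.30, 3.30, 3.40, 3.40, 3.50, 3.50, 3.50, 3.60,
                    3.60, 3.70, 3.70)

# The 15 m6A-containing stack classes, canonical representative names.
# A name t1 t2 b1 b2 denotes the duplex 5'-t1 t2-3' / 3'-b1 b2-5' with
# pairs (t1,b1) and (t2,b2); '6' is N6-methyladenosine and pairs U.
.THETA_NAMES <- c("6CUG", "UC6G", "6GUC", "UG6C", "6UUA", "6AUU", "UU6A",
                  "UA6U", "6UUG", "6UU6", "UG6U", "UU6G", "66UU", "6GUU",
                  "U66U")

#' Reference m6A stacking free energies
#'
#' The 15 experimentally determined m6A-containing nearest-neighbor
#' stacking free energies (optical melting, Kierzek et al. 2022,
#' 37 C, kcal/mol).  These serve as the ground-truth parameter set in
#' recovery experiments: base-pairing probabilities generated under
#' them define the training data the optimizer must invert.
#'
#' @return Named numeric vector of length 15 (kcal/mol), in the
#'   canonical stack-name order given by [thetaNames()].
#' @examples
#' gtTheta()[["6CUG"]]
#' @export
gtTheta <- function() {
  path <- system.file("extdata", "m6a_stacks_gt.tsv", package = "stackGrad")
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  th <- stats::setNames(tab$kcal_per_mol, tab$name)
  th[.THETA_NAMES]
}

#' Names of the trainable m6A stack parameters
#'
#' @return Character vector of the 15 canonical stack-class names.
#' @export
thetaNames <- function() .THETA_NAMES
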