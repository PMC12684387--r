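#' Default energy parameter set
#'
#' Returns an [EnergyParams-class] built from the embedded canonical
#' Turner 2004 constants, the linear multiloop model
#' (f3 = 9.3, f4 = 0.0, f5 = -0.9 kcal/mol) and a chosen m6A stack
#' vector theta.  Temperature is fixed at 37 C (T = 310.15 K,
#' RT = 0.6163 kcal/mol, beta = 1/RT).
#'
#' @param theta Either a named numeric(15) over [thetaNames()], or a
#'   single number replicated over all 15 entries.  Default -1.00, the
#'   optimizer's initial value.
#' @param minLoop Minimum hairpin loop size (default 3).
#' @return An [EnergyParams-class] object.
#' @examples
#' gt <- defaultEnergyParams(gtTheta())
#' theta(gt)[["6CUG"]]
#' @export
defaultEnergyParams <- function(theta = -1.00, minLoop = 3L) {
  RT <- 0.0019872 * 310.15
  if (length(theta) == 1L && is.null(names(theta)))
    theta <- stats::setNames(rep(as.numeric(theta), 15L), .THETA_NAMES)
  stopifnot(identical(sort(names(theta)), sort(.THETA_NAMES)))
  new("EnergyParams",
      theta = theta[.THETA_NAMES],
      canonicalStacks = .CANONICAL_STACKS,
      hairpinInit = .HAIRPIN_INIT,
      bulgeInit = .BULGE_INIT,
      internalInit = .INTERNAL_INIT,
      f3 = 9.30, f4 = 0.00, f5 = -0.90,
      beta = 1 / RT,
      minLoop = as.integer(minLoop))
}

#' Access or replace the trainable m6A stack parameters
#'
#' @param x An [EnergyParams-class] or [TrainResult-class] object.
#' @param value Named numeric(15) replacement (kcal/mol).
#' @return `theta` returns the named numeric(15) vector.
#' @name theta
NULL

#' @rdname theta
#' @export
setMethod("theta", "EnergyParams", function(x) x@theta)

#' @rdname theta
#' @export
setReplaceMethod("theta", "EnergyParams", function(x, value) {
  if (length(value) == 15L && is.null(names(value)))
    names(value) <- .THETA_NAMES
  x@theta[names(value)] <- value
  validObject(x)
  x
})

setMethod("show", "EnergyParams", function(object) {
  cat("EnergyParams (37 C, kcal/mol)\n")
  cat(sprintf("  multiloop: f3=%.2f f4=%.2f f5=%.2f;  min loop %d\n",
              object@f3, object@f4, object@f5, object@minLoop))
  cat("  m6A stacks (theta):\n")
  print(round(object@theta, 3))
})

# ---- pair rules -----------------------------------------------------------

# 5x5 allowed-pair matrix over A,C,G,U,6 (6 pairs U only)
.pairMatrix <- function() {
  p <- matrix(FALSE, 5, 5,
              dimnames = list(.STACKGRAD_ALPHABET, .STACKGRAD_ALPHABET))
  for (pp in c("AU", "GC", "GU", "6U")) {
    a <- substr(pp, 1, 1); b <- substr(pp, 2, 2)
    p[a, b] <- TRUE; p[b, a] <- TRUE
  }
  p
}

#' Is (x, y) an allowed base pair?
#'
#' Allowed pairs are AU, UA, GC, CG, GU, UG and the two m6A pairs 6U
#' and U6; the set is closed under reversal.
#'
#' @param x,y Single characters from \{A,C,G,U,6\}.
#' @return Logical.
#' @export
isPairable <- function(x, y) {
  p <- .pairMatrix()
  as.vector(p[cbind(match(toupper(x), .STACKGRAD_ALPHABET),
                    match(toupper(y), .STACKGRAD_ALPHABET))])
}

# ---- stack symmetry classes ----------------------------------------------

# Resolve the stack with outer pair (a, c), inner pair (b, d) (letters,
# name = a b c d reading the top strand 5'->3' and bottom 3'->5') to
# either a theta index (1..15) or 0 for a purely canonical stack.
# Returns NA for invalid geometry.
.stackClass <- function(a, b, c, d) {
  p <- .pairMatrix()
  if (!p[a, c] || !p[b, d]) return(NA_integer_)
  if (any(c(a, b, c, d) == "6")) {
    nm1 <- paste0(a, b, c, d)
    nm2 <- paste0(d, c, b, a)          # same duplex read from the other strand
    k <- match(nm1, .THETA_NAMES)
    if (is.na(k)) k <- match(nm2, .THETA_NAMES)
    return(k)
  }
  0L
}

# 5^4 lookup arrays consumed by the C++ core:
#   $thetaIndex: 0 canonical, 1..15 theta class, -1 invalid
#   $canonicalE: canonical stacking energy (0 where not canonical)
.stackLookup <- function(params) {
  al <- .STACKGRAD_ALPHABET
  idx <- array(-1L, dim = c(5, 5, 5, 5))
  ene <- array(0, dim = c(5, 5, 5, 5))
  pt <- function(x, y) match(paste0(x, y), .PAIR_TYPES)
  for (a in al) for (b in al) for (c in al) for (d in al) {
    k <- .stackClass(a, b, c, d)
    ia <- match(a, al); ib <- match(b, al)
    ic <- match(c, al); id <- match(d, al)
    if (is.na(k)) next
    idx[ia, ib, ic, id] <- k
    if (k == 0L)
      ene[ia, ib, ic, id] <- params@canonicalStacks[pt(a, c), pt(d, b)]
  }
  list(thetaIndex = idx, canonicalE = ene)
}

# Flat parameter list handed to the C++ routines
.params2cpp <- function(params) {
  lk <- .stackLookup(params)
  list(theta = unname(params@theta),
       stackTheta = as.integer(lk$thetaIndex),
       stackE = as.numeric(lk$canonicalE),
       pairable = matrix(as.integer(.pairMatrix()), 5, 5),
       hairpin = params@hairpinInit,
       bulge = params@bulgeInit,
       internal = params@internalInit,
       f3 = params@f3, f4 = params@f4, f5 = params@f5,
       beta = params@beta,
       minLoop = params@minLoop)
}

# ---- loop energies (R reference; the C++ core mirrors these) --------------

.loopExtrap <- function(tab, size, beta) {
  if (size < 1L) return(Inf)
  if (size <= 30L) return(tab[size])
  tab[30L] + 1.75 * (1 / beta) * log(size / 30)
}

#' Hairpin loop energy f1
#'
#' Energy of the hairpin closed by pair (i, j): a loop-length table
#' lookup with Jacobson-Stockmayer extrapolation
#' (E(n) = E(30) + 1.75 RT log(n/30)) beyond 30 nt.  The closing pair
#' must be allowed and the loop at least `minLoop` bases; hairpins carry
#' no trainable term, so the derivative with respect to theta is zero.
#'
#' @param seq Sequence ([ModRNA-class] or string).
#' @param i,j 1-based closing pair positions, i < j.
#' @param params [EnergyParams-class].
#' @return Energy in kcal/mol.
#' @export
hairpinEnergy <- function(seq, i, j, params = defaultEnergyParams()) {
  s <- strsplit(as.character(modRNA(seq)), "")[[1]]
  if (!isPairable(s[i], s[j]))
    stop(sprintf("(%d,%d) = %s%s is not pairable", i, j, s[i], s[j]))
  size <- j - i - 1L
  if (size < params@minLoop)
    stop(sprintf("hairpin loop of size %d below minimum %d", size,
                 params@minLoop))
  .loopExtrap(params@hairpinInit, size, params@beta)
}

#' Two-loop energy f2 (stack, bulge or internal loop)
#'
#' Energy of the loop delimited by outer pair (i, j) and inner pair
#' (h, l), i < h < l < j.  Adjacent pairs (h = i+1, l = j-1) form a
#' stack: a canonical Turner value, or one of the 15 trainable m6A
#' parameters when any of the four bases is m6A (both strand
#' orientations resolve to the same theta entry).  Otherwise the loop
#' is a bulge (one side empty) or internal loop, scored by total loop
#' length.
#'
#' @inheritParams hairpinEnergy
#' @param h,l Inner pair positions.
#' @return Energy in kcal/mol.
#' @export
twoLoopEnergy <- function(seq, i, j, h, l, params = defaultEnergyParams()) {
  s <- strsplit(as.character(modRNA(seq)), "")[[1]]
  if (!(i < h && h < l && l < j)) stop("need i < h < l < j")
  if (!isPairable(s[i], s[j]) || !isPairable(s[h], s[l]))
    stop("both (i,j) and (h,l) must be allowed pairs")
  if (h == i + 1L && l == j - 1L) {
    k <- .stackClass(s[i], s[h], s[j], s[l])
    if (k == 0L) {
      pt <- function(x, y) match(paste0(x, y), .PAIR_TYPES)
      return(params@canonicalStacks[pt(s[i], s[j]), pt(s[l], s[h])])
    }
    return(unname(params@theta[k]))
  }
  ll <- h - i - 1L; rl <- j - l - 1L
  if (ll == 0L || rl == 0L)
    .loopExtrap(params@bulgeInit, ll + rl, params@beta)
  else
    .loopExtrap(params@internalInit, ll + rl, params@beta)
}

#' Derivative of f2 with respect to each trainable parameter
#'
#' Indicator vector: 1 for the theta entry the stack (in either
#' orientation) resolves to, 0 elsewhere; identically 0 for bulges,
#' internal loops and purely canonical stacks.
#'
#' @inheritParams twoLoopEnergy
#' @return Named numeric(15) of 0/1 indicators.
#' @export
twoLoopThetaGrad <- function(seq, i, j, h, l, params = defaultEnergyParams()) {
  s <- strsplit(as.character(modRNA(seq)), "")[[1]]
  if (!(i < h && h < l && l < j)) stop("need i < h < l < j")
  g <- stats::setNames(numeric(15), .THETA_NAMES)
  if (h == i + 1L && l == j - 1L) {
    k <- .stackClass(s[i], s[h], s[j], s[l])
    if (!is.na(k) && k > 0L) g[k] <- 1
  }
  g
}

# ---- parameter TSV IO -----------------------------------------------------

#' Read / write energy parameter tables
#'
#' Plain TSV with columns `name` and `kcal_per_mol`: one row per m6A
#' stack entry plus the named constants F3, F4, F5.  Missing theta
#' entries default to `init` with a warning; unknown names are an
#' error.
#'
#' @param path File path.
#' @param init Default for theta entries absent from the file.
#' @return `readParams` returns an [EnergyParams-class].
#' @export
readParams <- function(path, init = -1.00) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "kcal_per_mol") %in% names(tab)))
  known <- c(.THETA_NAMES, "F3", "F4", "F5")
  unknown <- setdiff(tab$name, known)
  if (length(unknown))
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  th <- stats::setNames(rep(init, 15L), .THETA_NAMES)
  hit <- intersect(tab$name, .THETA_NAMES)
  th[hit] <- tab$kcal_per_mol[match(hit, tab$name)]
  if (length(hit) < 15L)
    warning(sprintf("%d theta entries missing; defaulting to %.2f",
                    15L - length(hit), init))
  p <- defaultEnergyParams(th)
  for (cn in c("F3", "F4", "F5"))
    if (cn %in% tab$name)
      slot(p, tolower(cn)) <- tab$kcal_per_mol[match(cn, tab$name)]
  p
}

#' @rdname readParams
#' @param params [EnergyParams-class] to serialize.
#' @export
writeParams <- function(params, path) {
  tab <- data.frame(
    name = c(names(params@theta), "F3", "F4", "F5"),
    kcal_per_mol = c(unname(params@theta), params@f3, params@f4, params@f5))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
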