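#' Construct a ModRNA sequence
#'
#' Builds a validated [ModRNA-class] object from a character string.
#' Lowercase input is normalized to uppercase; 'T' and any letter
#' outside \{A,C,G,U,6\} are rejected.
#'
#' @param x Character string (or a ModRNA, returned unchanged).
#' @return A [ModRNA-class] object.
#' @examples
#' modRNA("GG6AAAAUUCC")
#' @export
modRNA <- function(x) {
  if (is(x, "ModRNA")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  new("ModRNA", seq = toupper(x))
}

#' @describeIn modRNA Sequence length.
#' @export
setMethod("length", "ModRNA", function(x) nchar(x@seq))

#' @describeIn modRNA Coerce back to a plain string.
#' @export
setMethod("as.character", "ModRNA", function(x) x@seq)

setMethod("show", "ModRNA", function(object) {
  n <- nchar(object@seq)
  nm <- lengths(regmatches(object@seq, gregexpr("6", object@seq)))
  cat(sprintf("ModRNA of length %d (%d m6A)\n  %s\n", n, nm,
              if (n <= 60) object@seq
              else paste0(substr(object@seq, 1, 57), "...")))
})

# integer encoding A=1 C=2 G=3 U=4 6=5 used by the C++ core
.encodeSeq <- function(x) {
  x <- modRNA(x)
  m <- match(strsplit(x@seq, "")[[1]], .STACKGRAD_ALPHABET)
  as.integer(m)
}

.decodeSeq <- function(v) paste(.STACKGRAD_ALPHABET[v], collapse = "")
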