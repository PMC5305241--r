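# IUPAC nucleotide semantics shared by the primer matcher, the restriction-site
# scanner and the sequence validators. Each code maps to a 4-bit mask over
# {A,C,G,T}; two codes are compatible iff their masks intersect.

.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L,  # A/C
  R = 5L,  # A/G
  W = 9L,  # A/T
  S = 6L,  # C/G
  Y = 10L, # C/T
  K = 12L, # G/T
  V = 7L,  # A/C/G
  H = 11L, # A/C/T
  D = 13L, # A/G/T
  B = 14L, # C/G/T
  N = 15L
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M",
  V = "B", H = "D", D = "H", B = "V", N = "N", `-` = "-"
)

#' Split a nucleotide string into uppercase single characters
#'
#' Validates the alphabet against the IUPAC codes (optionally allowing the
#' alignment gap character) and reports the first offending position.
#'
#' @param seq A single character string.
#' @param allow_gap Logical; accept \code{'-'}?
#' @param what Label used in error messages.
#' @return Character vector of uppercase single-letter codes.
#' @keywords internal
.seqChars <- function(seq, allow_gap = FALSE, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  ok <- chars %in% names(.IUPAC_BITS)
  if (allow_gap) ok <- ok | chars == "-"
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("non-IUPAC character '%s' in %s at position %d",
                 chars[bad], what, bad), call. = FALSE)
  }
  chars
}

# Integer bit masks for a nucleotide string; gaps map to 0 (match nothing).
.seqBits <- function(seq, allow_gap = FALSE, what = "sequence") {
  chars <- .seqChars(seq, allow_gap = allow_gap, what = what)
  bits <- .IUPAC_BITS[chars]
  bits[is.na(bits)] <- 0L
  unname(bits)
}

#' Slide an IUPAC pattern along an IUPAC subject
#'
#' Returns, for every start offset, the number of incompatible positions
#' (empty intersection of the two codes' base sets). Used by both the primer
#' matcher and the restriction-site scanner; an independent brute-force
#' oracle re-derives the same quantity in the test suite.
#'
#' @param subjectBits,patternBits Integer bit-mask vectors from [.seqBits].
#' @return Integer vector of length \code{length(subject) - length(pattern) + 1}
#'   (zero-length when the pattern is longer than the subject).
#' @keywords internal
.slideMismatch <- function(subjectBits, patternBits) {
  ns <- length(subjectBits)
  np <- length(patternBits)
  if (np == 0L || np > ns) return(integer(0L))
  nstart <- ns - np + 1L
  mm <- integer(nstart)
  idx <- seq_len(nstart)
  for (j in seq_len(np)) {
    mm <- mm + as.integer(bitwAnd(subjectBits[idx + j - 1L], patternBits[j]) == 0L)
  }
  mm
}
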