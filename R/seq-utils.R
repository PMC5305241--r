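#' Reverse complement of an IUPAC nucleotide string
#'
#' Ambiguity codes map to their complements (R to Y, M to K, ...); the gap
#' character is preserved. The operation is an involution.
#'
#' @param seq A single nucleotide string (IUPAC alphabet, case-insensitive).
#' @return The reverse complement, uppercase.
#' @examples
#' revComp("AAGCTT")  # palindromic HindIII site
#' revComp("GGACT")
#' @export
revComp <- function(seq) {
  chars <- .seqChars(seq, allow_gap = TRUE)
  paste(rev(unname(.IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Translate a nucleotide string in a given reading frame
#'
#' Gaps are stripped before translation; a trailing partial codon is dropped.
#' Codons containing an ambiguity code are rendered as \code{'X'}; stop codons
#' as \code{'*'} (standard genetic code).
#'
#' @param seq A single nucleotide string.
#' @param frame Reading frame, 1, 2 or 3 (1-based offset into the sequence).
#' @return Single-letter amino-acid string.
#' @examples
#' translateSeq("GGACTGCTGAAGAAAGCTTAT")  # "GLLKKAY"
#' translateSeq("GGACTGCTGAAGAATGCTTAT")  # "GLLKNAY"
#' @export
translateSeq <- function(seq, frame = 1L) {
  if (!(length(frame) == 1L && frame %in% 1:3)) {
    stop("'frame' must be 1, 2 or 3", call. = FALSE)
  }
  chars <- .seqChars(seq, allow_gap = TRUE)
  chars <- chars[chars != "-"]
  if (length(chars) < frame) return("")
  chars <- chars[frame:length(chars)]
  ncodon <- length(chars) %/% 3L
  if (ncodon == 0L) return("")
  chars <- chars[seq_len(3L * ncodon)]
  dna <- Biostrings::DNAString(paste(chars, collapse = ""))
  as.character(Biostrings::translate(dna, if.fuzzy.codon = "X"))
}

#' Remove alignment gaps from a sequence
#'
#' @param seq A single nucleotide string possibly containing \code{'-'}.
#' @return The degapped string.
#' @export
degap <- function(seq) {
  gsub("-", "", seq, fixed = TRUE)
}

# as.character() drops names on character vectors; keep them.
.asNamedChar <- function(x) {
  nm <- names(x)
  out <- as.character(x)
  if (is.null(names(out))) names(out) <- nm
  out
}

# Deterministic per-stage substream seed: a string hash folded into the
# top-level seed, kept below 2^31 so set.seed() accepts it anywhere.
.stageSeed <- function(seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  as.integer(bitwXor(as.integer(seed %% 2147483647), as.integer(h)) %% 2147483647)
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
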