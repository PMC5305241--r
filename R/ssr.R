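# Microsatellite (SSR) mining with class-specific minimum repeat counts.
# The thresholds follow common EST-SSR practice for this assay family:
# mono >= 10, di >= 6, tri >= 4, tetra/penta/hexa >= 3.

#' Default SSR repeat-count thresholds by motif length
#' @return Named integer vector, names "1".."6".
#' @export
ssrThresholds <- function() {
  c(`1` = 10L, `2` = 6L, `3` = 4L, `4` = 3L, `5` = 3L, `6` = 3L)
}

#' Find microsatellite repeats in one sequence
#'
#' Scans periods 1-6 for maximal perfect tandem repeats meeting the
#' class-specific minimum repeat counts. A motif that is itself a repetition
#' of a shorter motif (e.g. "ATAT") is reported only at its shortest period;
#' 'N' and any ambiguity code break a repeat run. Overlapping hits of
#' different periods are all reported.
#'
#' @param seq A single nucleotide string (or \code{DNAString}).
#' @param thresholds Named vector mapping motif length ("1".."6") to the
#'   minimum repeat count; defaults to [ssrThresholds()].
#' @return A data.frame with columns \code{motif}, \code{repeats},
#'   \code{start}, \code{end} (1-based, inclusive), sorted by start.
#' @examples
#' findSSRs(paste0("GACGT", strrep("CTT", 4), "ACGTG"))
#' @export
findSSRs <- function(seq, thresholds = ssrThresholds()) {
  seq <- as.character(seq)
  if (!nzchar(seq)) {
    return(data.frame(motif = character(0), repeats = integer(0),
                      start = integer(0), end = integer(0)))
  }
  chars <- .seqChars(seq)
  n <- length(chars)
  plain <- chars %in% c("A", "C", "G", "T")
  hits <- list()
  for (p in 1:6) {
    minrep <- thresholds[[as.character(p)]]
    if (is.null(minrep) || is.na(minrep)) next
    if (n < p * minrep) next
    i <- seq_len(n - p)
    match <- chars[i] == chars[i + p] & plain[i]
    # maximal runs of consecutive period-p agreement
    r <- rle(match)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      a <- starts[k]
      len <- r$lengths[k] + p          # periodic region is [a, a+len-1]
      count <- len %/% p
      if (count < minrep) next
      motif <- paste(chars[a:(a + p - 1L)], collapse = "")
      if (.minimalPeriod(motif) < p) next  # reported at the shorter period
      hits[[length(hits) + 1L]] <- data.frame(
        motif = motif, repeats = as.integer(count),
        start = as.integer(a), end = as.integer(a + count * p - 1L))
    }
  }
  if (!length(hits)) {
    return(data.frame(motif = character(0), repeats = integer(0),
                      start = integer(0), end = integer(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, nchar(out$motif)), , drop = FALSE]
}

# Smallest q dividing nchar(motif) such that motif is (q-mer)^(p/q).
.minimalPeriod <- function(motif) {
  p <- nchar(motif)
  for (q in seq_len(p)) {
    if (p %% q != 0L) next
    unit <- substr(motif, 1L, q)
    if (strrep(unit, p %/% q) == motif) return(q)
  }
  p
}

#' Mine SSRs across a set of sequences
#'
#' @param seqs A named \code{DNAStringSet} or named character vector.
#' @param thresholds As in [findSSRs()].
#' @return A data.frame with a leading \code{seq_id} column.
#' @export
mineSSRs <- function(seqs, thresholds = ssrThresholds()) {
  seqs <- .asNamedChar(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  res <- lapply(seq_along(seqs), function(i) {
    h <- findSSRs(seqs[[i]], thresholds)
    if (nrow(h)) cbind(seq_id = ids[i], h) else NULL
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(seq_id = character(0), motif = character(0),
                      repeats = integer(0), start = integer(0),
                      end = integer(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
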