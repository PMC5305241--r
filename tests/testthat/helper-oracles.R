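# Independent brute-force oracles and small fixture builders. The oracles
# re-derive IUPAC semantics from explicit base sets so they share no code
# with the implementation they check.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"), D = c("A", "G", "T"),
  B = c("C", "G", "T"), N = c("A", "C", "G", "T"))

iupacCompatible <- function(a, b) {
  length(intersect(IUPAC_SETS[[a]], IUPAC_SETS[[b]])) > 0
}

# position-by-position degenerate pattern scan (plus strand only)
oracleScanPlus <- function(seq, pattern) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  n <- length(s); np <- length(p)
  if (np > n) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - np + 1)) {
    ok <- TRUE
    for (j in seq_len(np)) {
      if (!iupacCompatible(s[i + j - 1], p[j])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# exhaustive SSR search: every (start, period, count) triple, maximality and
# shortest-period reporting enforced by explicit checks
oracleSSRs <- function(seq, thresholds = capsScreen::ssrThresholds()) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  rows <- list()
  for (p in 1:6) {
    minrep <- thresholds[[as.character(p)]]
    for (start in seq_len(n)) {
      if (start + p * minrep - 1 > n) next
      motif <- s[start:(start + p - 1)]
      if (!all(motif %in% c("A", "C", "G", "T"))) next
      # smallest period of the motif must be p itself
      periodic <- FALSE
      for (q in seq_len(p - 1)) {
        if (p %% q == 0 &&
            all(motif == rep(motif[1:q], length.out = p))) periodic <- TRUE
      }
      if (periodic) next
      count <- 0
      repeat {
        a <- start + count * p
        if (a + p - 1 > n || !all(s[a:(a + p - 1)] == motif)) break
        count <- count + 1
      }
      if (count < minrep) next
      # maximal: not extendable left by one motif copy
      if (start - p >= 1 && all(s[(start - p):(start - 1)] == motif)) next
      # left-maximal within the period: previous base must not continue the run
      if (start > 1 && s[start - 1] == s[start - 1 + p]) next
      rows[[length(rows) + 1]] <- data.frame(
        motif = paste(motif, collapse = ""), repeats = as.integer(count),
        start = as.integer(start), end = as.integer(start + count * p - 1))
    }
  }
  if (!length(rows)) {
    return(data.frame(motif = character(0), repeats = integer(0),
                      start = integer(0), end = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, nchar(out$motif)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small labelled alignment from a character matrix of rows
toyAlignment <- function(rows, groups) {
  capsScreen::GroupedAlignment(
    Biostrings::DNAStringSet(rows), groups = groups)
}

# Table-3 codon contexts around the diagnostic SNP
CTX_DURA <- "GGACTGCTGAAGAAAGCTTAT"
CTX_PISIFERA <- "GGACTGCTGAAGAATGCTTAT"
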