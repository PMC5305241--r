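# In-silico PCR: IUPAC-aware primer binding and amplicon extraction.

#' Locate primer binding sites on a template
#'
#' Scans both strands with IUPAC-compatible matching (a template 'N' matches
#' anything). The primer's 3'-terminal base must match exactly regardless of
#' the mismatch allowance, mirroring polymerase extension requirements.
#'
#' @param template A single nucleotide string (or \code{DNAString}).
#' @param primer Primer sequence, 5'->3'.
#' @param maxMismatch Maximum tolerated mismatches elsewhere in the primer
#'   (default 0).
#' @return A data.frame with columns \code{position} (1-based start of the
#'   match on the top strand), \code{strand} ("+" or "-") and
#'   \code{mismatches}, sorted by position. A primer longer than the template
#'   yields zero rows.
#' @export
findBindingSites <- function(template, primer, maxMismatch = 0L) {
  stopifnot(maxMismatch >= 0L)
  tb <- .seqBits(as.character(template), what = "template")
  pchars <- .seqChars(as.character(primer), what = "primer")
  pb <- unname(.IUPAC_BITS[pchars])
  np <- length(pb)
  out <- list()

  mmPlus <- .slideMismatch(tb, pb)
  if (length(mmPlus)) {
    pos <- which(mmPlus <= maxMismatch)
    # 3' end of a plus-strand match is its last base
    pos <- pos[bitwAnd(tb[pos + np - 1L], pb[np]) > 0L]
    if (length(pos)) {
      out$plus <- data.frame(position = pos, strand = "+",
                             mismatches = mmPlus[pos])
    }
  }

  rcb <- unname(.IUPAC_BITS[.seqChars(revComp(paste(pchars, collapse = "")))])
  mmMinus <- .slideMismatch(tb, rcb)
  if (length(mmMinus)) {
    pos <- which(mmMinus <= maxMismatch)
    # 3' end of a minus-strand match sits at the first top-strand base
    pos <- pos[bitwAnd(tb[pos], rcb[1L]) > 0L]
    if (length(pos)) {
      out$minus <- data.frame(position = pos, strand = "-",
                              mismatches = mmMinus[pos])
    }
  }

  if (!length(out)) {
    return(data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract predicted PCR products from templates
#'
#' Every plus-strand forward-primer site is paired with every downstream
#' minus-strand reverse-primer site; products inside the size window are
#' reported. The product runs from the first base of the forward match to the
#' last base of the reverse match, so it begins with the forward primer and
#' ends with the reverse complement of the reverse primer.
#'
#' @param templates A named \code{DNAStringSet}, named character vector, or a
#'   single string.
#' @param pair A \linkS4class{PrimerPair}.
#' @param maxMismatch Mismatch allowance passed to [findBindingSites()].
#' @param minLen,maxLen Product size window in bp (defaults 100-2000).
#' @return A data.frame with columns \code{template_id}, \code{start},
#'   \code{end}, \code{length}, \code{seq}, sorted by template then start.
#'   No products is an empty data.frame, not an error.
#' @export
amplify <- function(templates, pair, maxMismatch = 0L,
                    minLen = 100L, maxLen = 2000L) {
  stopifnot(methods::is(pair, "PrimerPair"), minLen <= maxLen)
  templates <- .asNamedChar(templates)
  if (is.null(names(templates))) {
    names(templates) <- if (length(templates) == 1L) "template"
                        else as.character(seq_along(templates))
  }
  rlen <- nchar(pair@reverse)
  rows <- list()
  for (id in names(templates)) {
    tmpl <- templates[[id]]
    fsites <- findBindingSites(tmpl, pair@forward, maxMismatch)
    fsites <- fsites[fsites$strand == "+", , drop = FALSE]
    if (!nrow(fsites)) next
    rsites <- findBindingSites(tmpl, pair@reverse, maxMismatch)
    rsites <- rsites[rsites$strand == "-", , drop = FALSE]
    if (!nrow(rsites)) next
    for (f in fsites$position) {
      for (r in rsites$position) {
        if (r < f) next
        end <- r + rlen - 1L
        len <- end - f + 1L
        if (len < minLen || len > maxLen) next
        rows[[length(rows) + 1L]] <- data.frame(
          template_id = id, start = as.integer(f), end = as.integer(end),
          length = as.integer(len), seq = substr(tmpl, f, end))
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      seq = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$template_id, names(templates)), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# The single amplicon a marker assay expects; >1 product is surfaced loudly.
.singleAmplicon <- function(template, id, model, maxMismatch = 0L) {
  amp <- amplify(setNames(as.character(template), id), model@primers,
                 maxMismatch = maxMismatch)
  if (nrow(amp) == 0L) {
    stop(sprintf("no amplification product for '%s'", id), call. = FALSE)
  }
  if (nrow(amp) > 1L) {
    stop(sprintf("ambiguous amplification for '%s': %d products (lengths %s)",
                 id, nrow(amp), paste(amp$length, collapse = ", ")),
         call. = FALSE)
  }
  amp$seq[[1L]]
}
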