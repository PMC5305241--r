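# CAPS candidate discovery: differential restriction sites between two
# alleles near a variant, plus gel-practicality ranking.

#' Scan a sequence for restriction-enzyme recognition sites
#'
#' IUPAC-degenerate matching on the top strand; non-palindromic sites are
#' additionally scanned on the bottom strand and reported in top-strand
#' coordinates with strand "-".
#'
#' @param seq A gap-free nucleotide string (or \code{DNAString}).
#' @param enzyme A \linkS4class{RestrictionEnzyme}.
#' @return A data.frame with columns \code{position} (1-based site start) and
#'   \code{strand}, sorted by position. No sites is an empty data.frame.
#' @examples
#' scanSites("GGACTGCTGAAGAAAGCTTAT", hindIII())  # one site at 14
#' @export
scanSites <- function(seq, enzyme) {
  stopifnot(methods::is(enzyme, "RestrictionEnzyme"))
  seq <- as.character(seq)
  if (grepl("-", seq, fixed = TRUE)) {
    stop("'seq' must be gap-free; degap() it first", call. = FALSE)
  }
  sb <- .seqBits(seq)
  siteBits <- .seqBits(enzyme@site)
  pos <- which(.slideMismatch(sb, siteBits) == 0L)
  out <- data.frame(position = as.integer(pos),
                    strand = rep("+", length(pos)))
  if (!enzyme@palindromic) {
    rcBits <- .seqBits(revComp(enzyme@site))
    mpos <- which(.slideMismatch(sb, rcBits) == 0L)
    if (length(mpos)) {
      out <- rbind(out, data.frame(position = as.integer(mpos),
                                   strand = "-"))
    }
  }
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Discover CAPS candidates between two alleles
#'
#' For each enzyme, compares the recognition-site sets of the two (aligned,
#' gap-free, equal-length) alleles; a candidate is emitted iff the sets
#' differ and at least one differing site lies within \code{window} bp of a
#' position where the alleles differ. Fragment patterns for both alleles are
#' predicted by [digestSeq()].
#'
#' @param alleleA,alleleB Equal-length gap-free nucleotide strings differing
#'   at one or more positions.
#' @param enzymes List of \linkS4class{RestrictionEnzyme} objects (default:
#'   the shipped table).
#' @param window Maximum distance (bp) between a differing site and a
#'   differing base (default 30).
#' @return A data.frame with one row per candidate enzyme: \code{enzyme},
#'   \code{site}, \code{variant_pos} (nearest differing base),
#'   \code{site_pos} (start of the nearest differing recognition site),
#'   \code{differential} ("destroyed" if the site is lost going A to B,
#'   "created" if gained), \code{n_sites_A}, \code{n_sites_B},
#'   \code{min_fragment}, \code{separation} (smallest gel distance between
#'   fragments unique to one allele and fragments unique to the other), and
#'   list-columns \code{sites_A}, \code{sites_B}, \code{fragments_A},
#'   \code{fragments_B}.
#' @export
findCapsCandidates <- function(alleleA, alleleB,
                               enzymes = readEnzymeTable(), window = 30L) {
  a <- toupper(as.character(alleleA))
  b <- toupper(as.character(alleleB))
  if (nchar(a) != nchar(b)) {
    stop("alleles must have equal length (aligned, gap-free)", call. = FALSE)
  }
  ca <- .seqChars(a); cb <- .seqChars(b)
  diffs <- which(ca != cb)
  if (!length(diffs)) stop("alleles are identical", call. = FALSE)
  if (methods::is(enzymes, "RestrictionEnzyme")) enzymes <- list(enzymes)

  rows <- list()
  for (enz in enzymes) {
    sa <- scanSites(a, enz)
    sb <- scanSites(b, enz)
    keyA <- paste(sa$position, sa$strand)
    keyB <- paste(sb$position, sb$strand)
    onlyA <- sa[!(keyA %in% keyB), , drop = FALSE]
    onlyB <- sb[!(keyB %in% keyA), , drop = FALSE]
    if (!nrow(onlyA) && !nrow(onlyB)) next
    slen <- nchar(enz@site)
    near <- function(p) {
      # distance from a differing base to the recognition-site span
      min(pmax(0L, pmax(p - diffs, diffs - (p + slen - 1L))))
    }
    dOnlyA <- if (nrow(onlyA)) vapply(onlyA$position, near, numeric(1)) else numeric(0)
    dOnlyB <- if (nrow(onlyB)) vapply(onlyB$position, near, numeric(1)) else numeric(0)
    dmin <- suppressWarnings(min(c(dOnlyA, dOnlyB)))
    if (!is.finite(dmin) || dmin > window) next
    if (length(dOnlyA) && (!length(dOnlyB) || min(dOnlyA) <= min(dOnlyB))) {
      differential <- "destroyed"
      site_pos <- onlyA$position[which.min(dOnlyA)]
    } else {
      differential <- "created"
      site_pos <- onlyB$position[which.min(dOnlyB)]
    }
    variant_pos <- diffs[which.min(abs(diffs - (site_pos + slen %/% 2L)))]
    fragsA <- digestSeq(a, enz)
    fragsB <- digestSeq(b, enz)
    uniqA <- .msetDiff(fragsA, fragsB)
    uniqB <- .msetDiff(fragsB, fragsA)
    separation <- if (length(uniqA) && length(uniqB)) {
      min(abs(outer(uniqA, uniqB, "-")))
    } else 0
    row <- data.frame(enzyme = enz@name, site = enz@site,
                      variant_pos = as.integer(variant_pos),
                      site_pos = as.integer(site_pos),
                      differential = differential,
                      n_sites_A = nrow(sa), n_sites_B = nrow(sb),
                      min_fragment = min(c(fragsA, fragsB)),
                      separation = separation)
    row$sites_A <- list(sa$position)
    row$sites_B <- list(sb$position)
    row$fragments_A <- list(fragsA)
    row$fragments_B <- list(fragsB)
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) {
    out <- data.frame(enzyme = character(0), site = character(0),
                      variant_pos = integer(0), site_pos = integer(0),
                      differential = character(0), n_sites_A = integer(0),
                      n_sites_B = integer(0), min_fragment = numeric(0),
                      separation = numeric(0))
    out$sites_A <- list(); out$sites_B <- list()
    out$fragments_A <- list(); out$fragments_B <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# multiset difference: elements of x with multiplicities reduced by y
.msetDiff <- function(x, y) {
  for (v in y) {
    i <- match(v, x)
    if (!is.na(i)) x <- x[-i]
  }
  x
}

#' Rank CAPS candidates by gel practicality
#'
#' Candidates whose fragments are all at least \code{minFragment} bp and whose
#' allele-distinguishing fragments are separated by at least
#' \code{minSeparation} bp are retained and ranked first; ties are broken by
#' fewer total fragments, then enzyme name. Demoted candidates follow in the
#' same order.
#'
#' @param cands Output of [findCapsCandidates()].
#' @param minFragment Smallest gel-visible fragment (bp, default 80).
#' @param minSeparation Smallest resolvable band separation (bp, default 30).
#' @return \code{cands} reordered, with a logical \code{retained} column.
#' @export
rankCandidates <- function(cands, minFragment = 80L, minSeparation = 30L) {
  if (!nrow(cands)) {
    cands$retained <- logical(0)
    return(cands)
  }
  retained <- cands$min_fragment >= minFragment &
              cands$separation >= minSeparation
  nfrag <- lengths(cands$fragments_A) + lengths(cands$fragments_B)
  ord <- order(!retained, nfrag, cands$enzyme)
  out <- cands[ord, , drop = FALSE]
  out$retained <- retained[ord]
  rownames(out) <- NULL
  out
}
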