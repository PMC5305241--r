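# Variant-column discovery and classification in group-labelled alignments,
# plus codon-level effect annotation.

#' Find variant columns in an alignment
#'
#' A column is a variant iff it carries at least two distinct non-gap bases;
#' columns whose rows differ only by gaps are not variants.
#'
#' @param aln A \linkS4class{GroupedAlignment} with at least two sequences.
#' @return A data.frame with one row per variant column: \code{column}
#'   (1-based alignment index), \code{bases} (distinct non-gap bases,
#'   "/"-separated), and list-columns \code{alleles} (named per-sequence base,
#'   gaps as NA) and \code{degapped} (named per-sequence 1-based offset in the
#'   degapped sequence, NA where the row is gapped).
#' @export
findVariantColumns <- function(aln) {
  stopifnot(methods::is(aln, "GroupedAlignment"))
  if (length(aln) < 2L) {
    stop("variant detection needs at least two sequences", call. = FALSE)
  }
  mat <- .alnMatrix(aln)
  degap_off <- t(apply(mat != "-", 1L, cumsum))  # row-wise degapped offsets
  isVar <- apply(mat, 2L, function(col) {
    b <- unique(col[col != "-"])
    length(b) >= 2L
  })
  cols <- which(isVar)
  alleles <- lapply(cols, function(j) {
    a <- mat[, j]
    a[a == "-"] <- NA_character_
    a
  })
  degapped <- lapply(cols, function(j) {
    d <- degap_off[, j]
    d[mat[, j] == "-"] <- NA_integer_
    setNames(as.integer(d), rownames(mat))
  })
  bases <- vapply(alleles, function(a)
    paste(sort(unique(a[!is.na(a)])), collapse = "/"), character(1))
  out <- data.frame(column = as.integer(cols),
                    bases = as.character(bases))
  out$alleles <- alleles
  out$degapped <- degapped
  out
}

#' Classify a variant column as diagnostic, private or uninformative
#'
#' Diagnostic: the two reference groups are each fixed (100% within-group
#' agreement, gaps ignored) for different bases; sequences outside the
#' reference groups (e.g. heterozygote-derived haplotypes) do not enter the
#' fixation test. Private: exactly one sequence in the whole panel carries a
#' minor allele. Diagnostic takes precedence when both hold.
#'
#' @param alleles Named character vector of per-sequence bases (NA = gap).
#' @param groups Named character vector mapping sequence id to group label.
#' @param refGroups The two groups whose fixed difference defines
#'   "diagnostic" (default \code{c("dura", "pisifera")}).
#' @return A list with \code{classification} ("diagnostic", "private" or
#'   "uninformative"), \code{carrier} (sequence id for a private allele, else
#'   NA) and \code{groupAlleles} (list of observed bases per group).
#' @export
classifyColumn <- function(alleles, groups,
                           refGroups = c("dura", "pisifera")) {
  stopifnot(length(refGroups) == 2L)
  ids <- names(alleles)
  grp <- groups[ids]
  groupAlleles <- lapply(split(alleles[!is.na(alleles)],
                               grp[!is.na(alleles)]), unique)
  refBases <- lapply(refGroups, function(g) {
    members <- ids[!is.na(grp) & grp == g]
    if (!length(members)) {
      stop(sprintf("reference group '%s' has no members", g), call. = FALSE)
    }
    unique(alleles[members][!is.na(alleles[members])])
  })
  diagnostic <- length(refBases[[1L]]) == 1L && length(refBases[[2L]]) == 1L &&
    refBases[[1L]] != refBases[[2L]]
  if (diagnostic) {
    return(list(classification = "diagnostic", carrier = NA_character_,
                groupAlleles = groupAlleles))
  }
  counts <- table(alleles[!is.na(alleles)])
  if (length(counts) == 2L && min(counts) == 1L) {
    minor <- names(counts)[which.min(counts)]
    carrier <- ids[!is.na(alleles) & alleles == minor]
    return(list(classification = "private", carrier = carrier,
                groupAlleles = groupAlleles))
  }
  list(classification = "uninformative", carrier = NA_character_,
       groupAlleles = groupAlleles)
}

#' Transition or transversion?
#'
#' Purine-purine or pyrimidine-pyrimidine substitutions are transitions;
#' purine-pyrimidine substitutions are transversions (standard definition).
#'
#' @param ref,alt Single bases; an ambiguity code yields NA.
#' @return "transition", "transversion" or NA.
#' @export
mutationType <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  acgt <- c("A", "C", "G", "T")
  if (!(ref %in% acgt) || !(alt %in% acgt)) return(NA_character_)
  if (ref == alt) stop("'ref' and 'alt' must differ", call. = FALSE)
  purine <- c("A", "G")
  if ((ref %in% purine) == (alt %in% purine)) "transition" else "transversion"
}

#' Annotate the codon-level effect of a substitution
#'
#' Identifies the codon containing \code{pos} in the given reading frame,
#' substitutes the alternate base and translates both codons.
#'
#' @param seq Gap-free nucleotide string.
#' @param pos 1-based position of the substitution.
#' @param alt Alternate base (A/C/G/T).
#' @param frame Reading frame (1, 2 or 3).
#' @return A one-row data.frame: \code{pos}, \code{frame}, \code{codon_start},
#'   \code{codon_ref}, \code{codon_alt}, \code{aa_ref}, \code{aa_alt},
#'   \code{synonymous}.
#' @examples
#' annotateEffect("GGACTGCTGAAGAAAGCTTAT", 15, "T")  # AAA -> AAT, K -> N
#' @export
annotateEffect <- function(seq, pos, alt, frame = 1L) {
  seq <- toupper(as.character(seq))
  if (grepl("-", seq, fixed = TRUE)) {
    stop("'seq' must be gap-free; degap() it first", call. = FALSE)
  }
  n <- nchar(seq)
  stopifnot(pos >= 1L, pos <= n, frame %in% 1:3)
  alt <- toupper(alt)
  if (!(alt %in% c("A", "C", "G", "T"))) {
    stop("'alt' must be one of A, C, G, T", call. = FALSE)
  }
  if (pos < frame) {
    stop(sprintf("position %d precedes reading frame %d", pos, frame),
         call. = FALSE)
  }
  codon_start <- frame + 3L * ((pos - frame) %/% 3L)
  if (codon_start + 2L > n) {
    stop(sprintf("position %d falls in a trailing partial codon (frame %d)",
                 pos, frame), call. = FALSE)
  }
  codon_ref <- substr(seq, codon_start, codon_start + 2L)
  codon_alt <- codon_ref
  substr(codon_alt, pos - codon_start + 1L, pos - codon_start + 1L) <- alt
  aa_ref <- translateSeq(codon_ref)
  aa_alt <- translateSeq(codon_alt)
  data.frame(pos = as.integer(pos), frame = as.integer(frame),
             codon_start = as.integer(codon_start),
             codon_ref = codon_ref, codon_alt = codon_alt,
             aa_ref = aa_ref, aa_alt = aa_alt,
             synonymous = aa_ref == aa_alt)
}

#' Discover and classify all variant columns of a labelled alignment
#'
#' Convenience wrapper: [findVariantColumns()] then [classifyColumn()] and
#' transition/transversion annotation per column. Positions are reported both
#' as alignment columns and as degapped per-sequence offsets.
#'
#' @param aln A \linkS4class{GroupedAlignment}.
#' @param refGroups Passed to [classifyColumn()].
#' @return The [findVariantColumns()] data.frame with added columns
#'   \code{classification}, \code{carrier}, \code{ti_tv} (NA when more than
#'   two bases segregate).
#' @export
callVariants <- function(aln, refGroups = c("dura", "pisifera")) {
  vc <- findVariantColumns(aln)
  if (!nrow(vc)) {
    vc$classification <- character(0)
    vc$carrier <- character(0)
    vc$ti_tv <- character(0)
    return(vc)
  }
  groups <- alnGroups(aln)
  cls <- lapply(vc$alleles, classifyColumn, groups = groups,
                refGroups = refGroups)
  vc$classification <- vapply(cls, `[[`, character(1), "classification")
  vc$carrier <- vapply(cls, function(x) x$carrier[1L], character(1))
  vc$ti_tv <- vapply(vc$alleles, function(a) {
    b <- sort(unique(a[!is.na(a)]))
    if (length(b) != 2L) return(NA_character_)
    mutationType(b[1L], b[2L])
  }, character(1))
  vc
}
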