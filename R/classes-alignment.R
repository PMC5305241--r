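#' Group-labelled multiple sequence alignment
#'
#' A thin container pairing an aligned \linkS4class{DNAStringSet} (equal-width
#' rows, gap character \code{'-'}) with a per-sequence group label (for the
#' SHELL assay: \code{"dura"}, \code{"pisifera"}, \code{"tenera"} or
#' \code{"unknown"}). Heterozygous individuals are represented as two
#' haplotype rows, so every row carries exactly one base per column.
#'
#' @slot seqs A \code{DNAStringSet} of equal widths, names are sequence ids.
#' @slot groups Named character vector mapping every sequence id to a group
#'   label; ids absent from the label sheet default to \code{"unknown"}.
#'
#' @seealso [readAlignment()], [findVariantColumns()], [makePanel()]
#' @export
setClass("GroupedAlignment",
  representation(seqs = "DNAStringSet", groups = "character"))

setValidity("GroupedAlignment", function(object) {
  msgs <- character(0)
  w <- Biostrings::width(object@seqs)
  if (length(object@seqs) == 0L) {
    msgs <- c(msgs, "alignment must contain at least one sequence")
  } else if (length(unique(w)) != 1L) {
    msgs <- c(msgs, sprintf("alignment rows have unequal lengths: %s",
                            paste(w, collapse = ", ")))
  }
  ids <- names(object@seqs)
  if (is.null(ids) || anyDuplicated(ids)) {
    msgs <- c(msgs, "sequences must have unique names")
  } else if (!setequal(names(object@groups), ids)) {
    msgs <- c(msgs, "group labels must cover exactly the sequence ids")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GroupedAlignment
#'
#' @param seqs A named \code{DNAStringSet} (or named character vector) of
#'   equal-length aligned sequences.
#' @param groups Named character vector of group labels; ids not covered are
#'   labelled \code{"unknown"}.
#' @return A \linkS4class{GroupedAlignment}.
#' @export
GroupedAlignment <- function(seqs, groups = character(0)) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  ids <- names(seqs)
  if (is.null(ids)) stop("'seqs' must be named", call. = FALSE)
  full <- setNames(rep("unknown", length(ids)), ids)
  keep <- intersect(names(groups), ids)
  full[keep] <- unname(groups[keep])
  methods::new("GroupedAlignment", seqs = seqs, groups = full)
}

#' @describeIn GroupedAlignment-class Aligned sequences as a
#'   \code{DNAStringSet}.
#' @param x,object A \code{GroupedAlignment}.
#' @export
alnSeqs <- function(x) x@seqs

#' @describeIn GroupedAlignment-class Named character vector of group labels.
#' @export
alnGroups <- function(x) x@groups

#' @describeIn GroupedAlignment-class Number of rows.
#' @export
setMethod("length", "GroupedAlignment", function(x) length(x@seqs))

#' @describeIn GroupedAlignment-class Alignment width (columns).
#' @export
setMethod("ncol", "GroupedAlignment", function(x)
  if (length(x@seqs)) Biostrings::width(x@seqs)[1L] else 0L)

setMethod("show", "GroupedAlignment", function(object) {
  cat(sprintf("GroupedAlignment: %d sequences x %d columns\n",
              length(object@seqs), ncol(object)))
  tab <- table(object@groups)
  cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
})

# Alignment as a character matrix (rows = sequences, cols = columns).
.alnMatrix <- function(aln) {
  mat <- do.call(rbind, strsplit(as.character(alnSeqs(aln)), "", fixed = TRUE))
  rownames(mat) <- names(alnSeqs(aln))
  mat
}
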