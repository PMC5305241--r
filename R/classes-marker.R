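#' Primer pair
#'
#' Both primers are stored 5' to 3' as printed on an order sheet; the reverse
#' primer anneals to the plus strand as its reverse complement.
#'
#' @slot name Assay name.
#' @slot forward,reverse Primer sequences, 5'->3'.
#' @export
setClass("PrimerPair",
  representation(name = "character", forward = "character",
                 reverse = "character"))

setValidity("PrimerPair", function(object) {
  msgs <- character(0)
  if (!nzchar(object@forward) || !nzchar(object@reverse))
    msgs <- c(msgs, "both primers must be non-empty")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PrimerPair
#' @param name Assay name.
#' @param forward,reverse Primer sequences 5'->3' (IUPAC alphabet).
#' @return A \linkS4class{PrimerPair}.
#' @export
PrimerPair <- function(name, forward, reverse) {
  methods::new("PrimerPair", name = as.character(name),
    forward = paste(.seqChars(forward, what = "forward primer"), collapse = ""),
    reverse = paste(.seqChars(reverse, what = "reverse primer"), collapse = ""))
}

setMethod("show", "PrimerPair", function(object) {
  cat(sprintf("PrimerPair %s\n  F 5'-%s-3' (%d nt)\n  R 5'-%s-3' (%d nt)\n",
              object@name, object@forward, nchar(object@forward),
              object@reverse, nchar(object@reverse)))
})

#' The EgSHP primer pair used by the SHELL fruit-form assay
#'
#' Forward \code{TTGCTTTTAATTTTGCTTGAATACC} (25 nt), reverse
#' \code{TTTGGATCAGGGATAAAAGGGAAG} (24 nt); on the SHELL locus they bracket a
#' 550 bp product.
#'
#' @return A \linkS4class{PrimerPair}.
#' @export
egSHPPrimers <- function() {
  PrimerPair("EgSHP",
             forward = "TTGCTTTTAATTTTGCTTGAATACC",
             reverse = "TTTGGATCAGGGATAAAAGGGAAG")
}

#' CAPS marker model
#'
#' Everything needed to genotype a sample from its digest band pattern: the
#' primer pair, the differential enzyme, the amplicon length, which fruit-form
#' label is homozygous for the cut allele, and the expected gel band counts
#' per genotype class (one differential site: cut-hom 2 bands, uncut-hom 1,
#' het 3).
#'
#' @slot primers A \linkS4class{PrimerPair}.
#' @slot enzyme A \linkS4class{RestrictionEnzyme}.
#' @slot ampliconLength Expected product length (bp).
#' @slot cutLabel,uncutLabel,hetLabel Fruit-form labels for cut/cut,
#'   uncut/uncut and cut/uncut genotypes.
#' @slot expectedBands Named integer vector \code{c(cut=, uncut=, het=)}.
#' @slot tolerance Band-merge tolerance (bp) emulating gel resolution.
#' @export
setClass("MarkerModel",
  representation(primers = "PrimerPair", enzyme = "RestrictionEnzyme",
                 ampliconLength = "integer",
                 cutLabel = "character", uncutLabel = "character",
                 hetLabel = "character", expectedBands = "integer",
                 tolerance = "numeric"))

setValidity("MarkerModel", function(object) {
  msgs <- character(0)
  labs <- c(object@cutLabel, object@uncutLabel, object@hetLabel)
  if (anyDuplicated(labs)) msgs <- c(msgs, "genotype labels must be distinct")
  if (!all(c("cut", "uncut", "het") %in% names(object@expectedBands)))
    msgs <- c(msgs, "expectedBands needs entries 'cut', 'uncut', 'het'")
  else {
    eb <- object@expectedBands
    if (eb[["uncut"]] != 1L || eb[["het"]] != eb[["cut"]] + 1L)
      msgs <- c(msgs,
        "band counts inconsistent with a single differential site")
  }
  if (object@ampliconLength < 1L) msgs <- c(msgs, "ampliconLength must be >= 1")
  if (object@tolerance < 0) msgs <- c(msgs, "tolerance must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MarkerModel
#'
#' @param primers A \linkS4class{PrimerPair}.
#' @param enzyme A \linkS4class{RestrictionEnzyme}.
#' @param ampliconLength Expected amplicon length in bp.
#' @param cutLabel,uncutLabel,hetLabel Genotype class labels (defaults: the
#'   oil palm fruit forms dura / pisifera / tenera).
#' @param expectedBands Named integer vector of expected band counts.
#' @param tolerance Band-merge tolerance in bp (default 15, agarose-like).
#' @return A \linkS4class{MarkerModel}.
#' @export
MarkerModel <- function(primers, enzyme, ampliconLength = 550L,
                        cutLabel = "dura", uncutLabel = "pisifera",
                        hetLabel = "tenera",
                        expectedBands = c(cut = 2L, uncut = 1L, het = 3L),
                        tolerance = 15) {
  methods::new("MarkerModel", primers = primers, enzyme = enzyme,
    ampliconLength = as.integer(ampliconLength),
    cutLabel = cutLabel, uncutLabel = uncutLabel, hetLabel = hetLabel,
    expectedBands = setNames(as.integer(expectedBands), names(expectedBands)),
    tolerance = as.numeric(tolerance))
}

#' The default SHELL CAPS marker model (EgSHP + HindIII, 550 bp)
#' @param tolerance Band-merge tolerance in bp.
#' @return A \linkS4class{MarkerModel}.
#' @export
shellMarkerModel <- function(tolerance = 15) {
  MarkerModel(egSHPPrimers(), hindIII(), ampliconLength = 550L,
              tolerance = tolerance)
}

setMethod("show", "MarkerModel", function(object) {
  cat(sprintf(
    "MarkerModel: %s + %s, %d bp product\n  %s = cut/cut, %s = uncut/uncut, %s = cut/uncut; band tolerance %g bp\n",
    object@primers@name, object@enzyme@name, object@ampliconLength,
    object@cutLabel, object@uncutLabel, object@hetLabel, object@tolerance))
})

#' Gel-resolvable band pattern of a diploid digest
#'
#' Fragments from the two haplotype digests are pooled and single-linkage
#' merged: fragments closer than the tolerance co-migrate as one band whose
#' representative length is the longest member.
#'
#' @slot bands Sorted (decreasing) representative band lengths.
#' @slot members List (parallel to \code{bands}) of the exact fragment lengths
#'   contributing to each band.
#' @slot tolerance Merge tolerance (bp).
#' @export
setClass("BandPattern",
  representation(bands = "numeric", members = "list", tolerance = "numeric"))

setValidity("BandPattern", function(object) {
  msgs <- character(0)
  if (length(object@bands) != length(object@members))
    msgs <- c(msgs, "'bands' and 'members' lengths differ")
  if (length(object@bands) == 0L)
    msgs <- c(msgs, "a band pattern must contain at least one band")
  if (is.unsorted(rev(object@bands)))
    msgs <- c(msgs, "'bands' must be sorted decreasing")
  if (length(object@bands) > 1L &&
      any(abs(diff(object@bands)) <= object@tolerance))
    msgs <- c(msgs, "adjacent bands must differ by more than the tolerance")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn BandPattern-class Representative band lengths (decreasing).
#' @param x,object A \code{BandPattern}.
#' @export
bands <- function(x) x@bands

#' @describeIn BandPattern-class Number of gel-resolvable bands.
#' @export
setMethod("length", "BandPattern", function(x) length(x@bands))

setMethod("show", "BandPattern", function(object) {
  cat(sprintf("BandPattern (%d bands, tolerance %g bp): %s\n",
              length(object@bands), object@tolerance,
              paste(object@bands, collapse = " / ")))
})
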