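# In-silico restriction digestion, diploid band patterns, fruit-form calling
# and cohort screening with Mendelian segregation checks.

#' Digest a linear sequence with a restriction enzyme
#'
#' Each recognition site contributes one double-strand cut on the top strand:
#' after \code{site_start - 1 + cutTop} bases for a plus-strand site, mirrored
#' for a minus-strand site of a non-palindromic enzyme. Cuts falling outside
#' the sequence (possible for type-IIS enzymes near an end) are dropped.
#' Fragment lengths always sum to the sequence length.
#'
#' @param seq Gap-free nucleotide string (a linear PCR product).
#' @param enzyme A \linkS4class{RestrictionEnzyme}.
#' @return Numeric vector of fragment lengths in sequence order; an uncut
#'   sequence yields a single full-length fragment.
#' @export
digestSeq <- function(seq, enzyme) {
  seq <- as.character(seq)
  n <- nchar(seq)
  sites <- scanSites(seq, enzyme)
  if (!nrow(sites)) return(n)
  slen <- nchar(enzyme@site)
  cutAfter <- ifelse(sites$strand == "+",
                     sites$position - 1L + enzyme@cutTop,
                     sites$position + slen - 1L - enzyme@cutTop)
  cutAfter <- sort(unique(cutAfter[cutAfter >= 1L & cutAfter <= n - 1L]))
  if (!length(cutAfter)) return(n)
  diff(c(0L, cutAfter, n))
}

#' Merge two haplotype digests into a gel band pattern
#'
#' Pools the fragments of both haplotypes and single-linkage merges fragments
#' within the tolerance into one band (representative length = longest
#' member), emulating agarose resolution.
#'
#' @param fragsA,fragsB Fragment length vectors from [digestSeq()].
#' @param tolerance Merge tolerance in bp (default 15).
#' @return A \linkS4class{BandPattern}.
#' @export
diploidBandPattern <- function(fragsA, fragsB, tolerance = 15) {
  stopifnot(tolerance >= 0)
  if (!length(fragsA) || !length(fragsB)) {
    stop("both haplotype digests must contain at least one fragment",
         call. = FALSE)
  }
  frags <- sort(c(fragsA, fragsB))
  cluster <- cumsum(c(1, diff(frags) > tolerance))
  members <- split(frags, cluster)
  reps <- vapply(members, max, numeric(1))
  ord <- order(reps, decreasing = TRUE)
  methods::new("BandPattern", bands = unname(reps[ord]),
               members = unname(members[ord]), tolerance = tolerance)
}

#' Call the fruit form from a band pattern
#'
#' Full-length band only: uncut homozygote. Cut fragments only (band count
#' matching the model's cut-homozygote expectation): cut homozygote.
#' Full-length band plus the expected cut fragments: heterozygote. Anything
#' else: \code{"unresolved"} (a value, not an error).
#'
#' @param pattern A \linkS4class{BandPattern}.
#' @param model A \linkS4class{MarkerModel}.
#' @return One of the model's three genotype labels or \code{"unresolved"}.
#' @export
callFruitForm <- function(pattern, model) {
  stopifnot(methods::is(pattern, "BandPattern"),
            methods::is(model, "MarkerModel"))
  b <- bands(pattern)
  tol <- pattern@tolerance
  hasFull <- any(abs(b - model@ampliconLength) <= tol)
  nCut <- sum(b < model@ampliconLength - tol)
  eb <- model@expectedBands
  if (hasFull && nCut == 0L && length(b) == eb[["uncut"]]) {
    return(model@uncutLabel)
  }
  if (!hasFull && length(b) == eb[["cut"]]) {
    return(model@cutLabel)
  }
  if (hasFull && length(b) == eb[["het"]] && nCut == eb[["het"]] - 1L) {
    return(model@hetLabel)
  }
  "unresolved"
}

#' Genotype one diploid sample from its two haplotype sequences
#'
#' @param hapA,hapB Haplotype sequences: templates carrying the marker's
#'   primer sites, or ready-made amplicons when \code{amplified = TRUE}.
#' @param model A \linkS4class{MarkerModel}.
#' @param amplified If \code{FALSE} (default), each haplotype is first
#'   amplified in silico with the model's primers; exactly one product per
#'   haplotype is required.
#' @param tolerance Band-merge tolerance; defaults to the model's.
#' @return A list: \code{call}, \code{pattern} (a
#'   \linkS4class{BandPattern}), \code{fragments} (per-haplotype list).
#' @export
genotypeSample <- function(hapA, hapB, model, amplified = FALSE,
                           tolerance = model@tolerance) {
  if (!amplified) {
    hapA <- .singleAmplicon(hapA, "haplotype A", model)
    hapB <- .singleAmplicon(hapB, "haplotype B", model)
  }
  fragsA <- digestSeq(hapA, model@enzyme)
  fragsB <- digestSeq(hapB, model@enzyme)
  pattern <- diploidBandPattern(fragsA, fragsB, tolerance)
  list(call = callFruitForm(pattern, model), pattern = pattern,
       fragments = list(A = fragsA, B = fragsB))
}

#' Cohort screening result
#'
#' Per-sample fruit-form calls plus a chi-square goodness-of-fit of the
#' observed genotype-class counts against the Mendelian expectation of the
#' cross (\code{DxP}: all heterozygous; \code{TxT}: 1:2:1).
#'
#' @slot calls data.frame: \code{sample_id}, \code{call}, \code{bands}.
#' @slot cross "DxP", "TxT" or "none".
#' @slot observed Named integer counts over the model's genotype classes
#'   (plus "unresolved").
#' @slot expected Named numeric expected counts (resolved samples only).
#' @slot chisq,df,pValue Goodness-of-fit test (NA when \code{cross="none"}).
#' @slot contamination Sample ids whose call contradicts the cross (for DxP,
#'   every non-heterozygote call).
#' @export
setClass("CohortResult",
  representation(calls = "data.frame", cross = "character",
                 observed = "integer", expected = "numeric",
                 chisq = "numeric", df = "integer", pValue = "numeric",
                 contamination = "character"))

setValidity("CohortResult", function(object) {
  if (sum(object@observed) != nrow(object@calls)) {
    return("class counts must sum to the cohort size")
  }
  TRUE
})

setMethod("show", "CohortResult", function(object) {
  cat(sprintf("CohortResult: %d samples, cross %s\n", nrow(object@calls),
              object@cross))
  cat("  observed:",
      paste(sprintf("%s=%d", names(object@observed), object@observed),
            collapse = ", "), "\n")
  if (!is.na(object@chisq)) {
    cat(sprintf("  chi-square %.4g on %d df, p = %.4g\n", object@chisq,
                object@df, object@pValue))
  }
  if (length(object@contamination)) {
    cat("  contamination flags:", paste(object@contamination, collapse = ", "),
        "\n")
  }
})

#' @describeIn CohortResult-class Per-sample calls as a data.frame.
#' @param x,object A \code{CohortResult}.
#' @export
cohortCalls <- function(x) x@calls

#' @describeIn CohortResult-class Segregation test as a one-row data.frame.
#' @export
segregationTest <- function(x) {
  data.frame(cross = x@cross, n = nrow(x@calls), chisq = x@chisq, df = x@df,
             p_value = x@pValue, n_contamination = length(x@contamination))
}

#' Screen a cohort of diploid samples with a CAPS marker
#'
#' Each sample's two haplotypes are amplified (unless already amplicons),
#' digested and merged into a band pattern; the fruit-form calls are then
#' tested against the Mendelian expectation of the stated cross:
#' dura x pisifera (\code{"DxP"}) segregates all-heterozygote, tenera x tenera
#' (\code{"TxT"}) segregates 1:2:1 cut-hom : het : uncut-hom. Unresolved calls
#' are excluded from the chi-square and flagged.
#'
#' @param haplotypes Named \code{DNAStringSet} or named character vector of
#'   haplotype sequences.
#' @param samples data.frame with columns \code{sample_id}, \code{hap1},
#'   \code{hap2} (haplotype sequence names).
#' @param model A \linkS4class{MarkerModel}.
#' @param cross "DxP", "TxT" or "none" (no segregation expectation).
#' @param amplified Passed to [genotypeSample()].
#' @param tolerance Band-merge tolerance; defaults to the model's.
#' @return A \linkS4class{CohortResult}.
#' @export
screenCohort <- function(haplotypes, samples, model,
                         cross = c("none", "DxP", "TxT"), amplified = FALSE,
                         tolerance = model@tolerance) {
  if (is.character(cross) && length(cross) == 1L &&
      !(cross %in% c("none", "DxP", "TxT"))) {
    stop(sprintf("unknown cross label '%s' (expected DxP, TxT or none)",
                 cross), call. = FALSE)
  }
  cross <- match.arg(cross)
  need <- c("sample_id", "hap1", "hap2")
  if (!all(need %in% names(samples))) {
    stop("'samples' needs columns sample_id, hap1, hap2", call. = FALSE)
  }
  haplotypes <- .asNamedChar(haplotypes)
  missing <- setdiff(unique(c(samples$hap1, samples$hap2)), names(haplotypes))
  if (length(missing)) {
    stop("haplotype sequences missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  gts <- lapply(seq_len(nrow(samples)), function(i) {
    genotypeSample(haplotypes[[samples$hap1[i]]],
                   haplotypes[[samples$hap2[i]]],
                   model, amplified = amplified, tolerance = tolerance)
  })
  calls <- vapply(gts, `[[`, character(1), "call")
  bandStr <- vapply(gts, function(gt)
    paste(bands(gt$pattern), collapse = "/"), character(1))
  callsDf <- data.frame(sample_id = samples$sample_id, call = calls,
                        bands = bandStr)
  classes <- c(model@cutLabel, model@hetLabel, model@uncutLabel, "unresolved")
  observed <- setNames(
    as.integer(table(factor(calls, levels = classes))), classes)

  ratio <- switch(cross,
    DxP = setNames(c(0, 1, 0), classes[1:3]),
    TxT = setNames(c(0.25, 0.5, 0.25), classes[1:3]),
    none = NULL)
  if (is.null(ratio)) {
    chisq <- NA_real_; df <- NA_integer_; p <- NA_real_
    contamination <- character(0)
  } else {
    resolved <- observed[classes[1:3]]
    nres <- sum(resolved)
    expected <- ratio * nres
    pos <- expected > 0
    offClass <- sum(resolved[!pos])
    if (offClass > 0) {
      chisq <- Inf; p <- 0
    } else {
      chisq <- sum((resolved[pos] - expected[pos])^2 / expected[pos])
      df0 <- as.integer(sum(pos) - 1L)
      p <- if (df0 == 0L) {
        if (chisq == 0) 1 else 0
      } else {
        stats::pchisq(chisq, df0, lower.tail = FALSE)
      }
    }
    df <- as.integer(sum(pos) - 1L)
    contamination <- if (cross == "DxP") {
      callsDf$sample_id[callsDf$call != model@hetLabel]
    } else {
      callsDf$sample_id[callsDf$call == "unresolved"]
    }
  }
  methods::new("CohortResult", calls = callsDf, cross = cross,
               observed = observed,
               expected = if (is.null(ratio)) numeric(0)
                          else ratio * sum(observed[classes[1:3]]),
               chisq = chisq, df = df, pValue = p,
               contamination = as.character(contamination))
}
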