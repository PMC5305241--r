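#' Restriction enzyme
#'
#' Recognition site as an IUPAC string plus cut offsets measured in bases from
#' the 5' end of the site on each strand ("cut after this many bases"). A
#' within-site cutter like HindIII (A^AGCTT) has \code{cutTop = 1},
#' \code{cutBottom = 5}; a type-IIS enzyme cutting downstream of its site
#' (e.g. MboII, GAAGA(8/7)) carries offsets beyond the site length and is
#' flagged \code{typeIIS}.
#'
#' @slot name Enzyme name.
#' @slot site IUPAC recognition sequence (length >= 4).
#' @slot cutTop,cutBottom Integer cut offsets from the site start on the top
#'   and bottom strand.
#' @slot palindromic Whether the site equals its reverse complement.
#' @slot typeIIS Whether either offset falls outside the recognition site.
#' @export
setClass("RestrictionEnzyme",
  representation(name = "character", site = "character",
                 cutTop = "integer", cutBottom = "integer",
                 palindromic = "logical", typeIIS = "logical"))

setValidity("RestrictionEnzyme", function(object) {
  msgs <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "'name' must be a non-empty string")
  if (length(object@site) != 1L || nchar(object@site) < 4L)
    msgs <- c(msgs, "recognition site must be at least 4 nt")
  if (length(object@cutTop) != 1L || length(object@cutBottom) != 1L ||
      is.na(object@cutTop) || is.na(object@cutBottom))
    msgs <- c(msgs, "cut offsets must be single integers")
  else if (object@cutTop < 0L || object@cutBottom < 0L)
    msgs <- c(msgs, "cut offsets must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a RestrictionEnzyme
#'
#' @param name Enzyme name.
#' @param site IUPAC recognition site.
#' @param cutTop,cutBottom Cut offsets (bases from site start, per strand).
#' @return A \linkS4class{RestrictionEnzyme}.
#' @examples
#' hindIII <- RestrictionEnzyme("HindIII", "AAGCTT", 1, 5)
#' @export
RestrictionEnzyme <- function(name, site, cutTop, cutBottom) {
  site <- paste(.seqChars(site, what = sprintf("site of %s", name)),
                collapse = "")
  methods::new("RestrictionEnzyme",
    name = as.character(name), site = site,
    cutTop = as.integer(cutTop), cutBottom = as.integer(cutBottom),
    palindromic = identical(site, revComp(site)),
    typeIIS = as.integer(cutTop) > nchar(site) ||
              as.integer(cutBottom) > nchar(site))
}

#' @describeIn RestrictionEnzyme-class Enzyme name.
#' @param x,object A \code{RestrictionEnzyme}.
#' @export
enzymeName <- function(x) x@name

#' @describeIn RestrictionEnzyme-class IUPAC recognition site.
#' @export
enzymeSite <- function(x) x@site

setMethod("show", "RestrictionEnzyme", function(object) {
  cat(sprintf("RestrictionEnzyme %s: %s (cut %d/%d%s%s)\n", object@name,
              object@site, object@cutTop, object@cutBottom,
              if (object@palindromic) ", palindromic" else "",
              if (object@typeIIS) ", type IIS" else ""))
})

#' Read a REBASE-like enzyme table
#'
#' Tab-separated with header columns \code{name}, \code{site}, \code{cut_top},
#' \code{cut_bottom}.
#'
#' @param path Path to the table. Defaults to the table shipped with the
#'   package (HindIII plus the other four enzymes screened for the SHELL
#'   assay: BseMII, MboII, EcoP15I, NaeI).
#' @return Named list of \linkS4class{RestrictionEnzyme} objects.
#' @export
readEnzymeTable <- function(path = defaultEnzymeFile()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "site", "cut_top", "cut_bottom")
  if (!all(need %in% names(tab))) {
    stop("enzyme table must have columns name, site, cut_top, cut_bottom: ",
         path, call. = FALSE)
  }
  enz <- lapply(seq_len(nrow(tab)), function(i) {
    RestrictionEnzyme(tab$name[i], tab$site[i], tab$cut_top[i],
                      tab$cut_bottom[i])
  })
  setNames(enz, tab$name)
}

#' Path of the enzyme table shipped with the package
#' @return File path.
#' @export
defaultEnzymeFile <- function() {
  system.file("extdata", "enzymes.tsv", package = "capsScreen",
              mustWork = TRUE)
}

#' The HindIII enzyme (A^AGCTT)
#' @return A \linkS4class{RestrictionEnzyme}.
#' @export
hindIII <- function() RestrictionEnzyme("HindIII", "AAGCTT", 1L, 5L)
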