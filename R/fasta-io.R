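#' Read a (multi-)FASTA file of nucleotide sequences
#'
#' @param path Path to a FASTA file.
#' @return A named \code{DNAStringSet}, uppercase.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(ss) == 0L) stop("empty FASTA input: ", path, call. = FALSE)
  # record ids are the first whitespace-delimited token; keep the rest as-is
  names(ss) <- sub("\\s.*$", "", names(ss))
  Biostrings::DNAStringSet(toupper(as.character(ss)), use.names = TRUE)
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs A named \code{DNAStringSet} or named character vector.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path, width = 60L)
  invisible(path)
}

#' Read a multiple sequence alignment (aligned FASTA or CLUSTAL)
#'
#' Rows must have equal length; a ragged alignment is a format error that
#' reports every row length. Group labels may be supplied as a named vector or
#' as a tab-separated sample sheet with columns \code{sample_id} and
#' \code{group}; unlabelled sequences default to \code{"unknown"}.
#'
#' @param path Path to the alignment file.
#' @param dialect \code{"auto"} (sniff the first line), \code{"fasta"} or
#'   \code{"clustal"}.
#' @param labels Named character vector of group labels, or path to a
#'   tab-separated sheet.
#' @return A \linkS4class{GroupedAlignment}.
#' @export
readAlignment <- function(path, dialect = c("auto", "fasta", "clustal"),
                          labels = character(0)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (length(first) == 0L) stop("empty alignment input: ", path, call. = FALSE)
    dialect <- if (grepl("^CLUSTAL", first, ignore.case = TRUE)) "clustal"
               else "fasta"
  }
  if (dialect == "clustal") {
    a <- seqinr::read.alignment(path, format = "clustal")
    seqs <- setNames(toupper(unlist(a$seq)), a$nam)
  } else {
    ss <- Biostrings::readBStringSet(path, format = "fasta")
    if (length(ss) == 0L) stop("empty alignment input: ", path, call. = FALSE)
    seqs <- setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop(sprintf("ragged alignment in %s: row lengths %s", path,
                 paste(lens, collapse = ", ")), call. = FALSE)
  }
  if (is.character(labels) && length(labels) == 1L && is.null(names(labels)) &&
      file.exists(labels)) {
    labels <- readSampleGroups(labels)
  }
  GroupedAlignment(Biostrings::DNAStringSet(seqs), groups = labels)
}

#' Read a two-column sample sheet of group labels
#'
#' @param path Tab-separated file with header columns \code{sample_id} and
#'   \code{group} (extra columns ignored).
#' @return Named character vector id -> group.
#' @export
readSampleGroups <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(tab))) {
    stop("sample sheet must have columns 'sample_id' and 'group': ", path,
         call. = FALSE)
  }
  setNames(as.character(tab$group), as.character(tab$sample_id))
}
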