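# Seeded synthetic-cohort generator: amplicon alleles carrying the planted
# diagnostic and private SNPs, flanked templates, diploid individuals and
# cross progenies, so every pipeline stage runs without external data.

# 21-nt codon context around the diagnostic SNP; the cut allele's 'A' (offset
# 15) completes the single HindIII site (offset 14-19), the uncut allele's 'T'
# destroys it. Translations: GLLKKAY (cut) vs GLLKNAY (uncut).
.CTX_CUT <- "GGACTGCTGAAGAAAGCTTAT"
.CTX_SNP_OFFSET <- 15L

#' Synthetic-cohort generator configuration
#'
#' Defaults emulate the SHELL assay's amplicon: a 550 bp product bracketed by
#' the EgSHP primers, one group-diagnostic SNP at position 248 (cut allele
#' 'A' creates the single HindIII site spanning it; uncut allele 'T' has
#' none) and one private SNP at position 169 (G, with a single cut-allele
#' carrier bearing 'A'). Background sequence is uniform random and scrubbed
#' of spurious enzyme sites and primer matches.
#'
#' @slot ampliconLength,diagnosticPos,privatePos,flankLength Integer geometry
#'   (bp, 1-based amplicon coordinates).
#' @slot cutBase,uncutBase,privateMajor,privateMinor Planted bases.
#' @slot privateCarrier Id of the cut-homozygote individual carrying the
#'   private allele in panel alignments.
#' @slot errorRate Per-base substitution rate applied to emitted haplotype
#'   copies (primer landing sites and planted SNP positions are never
#'   touched).
#' @slot seed Top-level seed; all stages draw from named substreams of it.
#' @slot primers,enzyme The assay the generator plants sites for.
#' @export
setClass("GeneratorConfig",
  representation(ampliconLength = "integer", diagnosticPos = "integer",
                 cutBase = "character", uncutBase = "character",
                 privatePos = "integer", privateMajor = "character",
                 privateMinor = "character", privateCarrier = "character",
                 flankLength = "integer", errorRate = "numeric",
                 seed = "integer", primers = "PrimerPair",
                 enzyme = "RestrictionEnzyme"))

setValidity("GeneratorConfig", function(object) {
  msgs <- character(0)
  L <- object@ampliconLength
  fl <- nchar(object@primers@forward)
  rl <- nchar(object@primers@reverse)
  ctxStart <- object@diagnosticPos - .CTX_SNP_OFFSET + 1L
  ctxEnd <- ctxStart + nchar(.CTX_CUT) - 1L
  if (L < fl + rl + nchar(.CTX_CUT) + 2L)
    msgs <- c(msgs, "amplicon too short for primers and SNP context")
  if (ctxStart <= fl || ctxEnd > L - rl)
    msgs <- c(msgs, sprintf(
      "diagnostic_pos %d infeasible: SNP context (columns %d-%d) must lie between the primer regions (%d..%d)",
      object@diagnosticPos, ctxStart, ctxEnd, fl + 1L, L - rl))
  pp <- object@privatePos
  if (pp <= fl || pp > L - rl || (pp >= ctxStart && pp <= ctxEnd))
    msgs <- c(msgs,
      "private_pos must lie between the primers and outside the SNP context")
  if (object@errorRate < 0 || object@errorRate > 1)
    msgs <- c(msgs, "errorRate must be in [0, 1]")
  if (object@flankLength < 0L) msgs <- c(msgs, "flankLength must be >= 0")
  bases <- c(object@cutBase, object@uncutBase, object@privateMajor,
             object@privateMinor)
  if (!all(bases %in% c("A", "C", "G", "T")))
    msgs <- c(msgs, "planted bases must be A, C, G or T")
  if (object@cutBase != "A" || object@uncutBase != "T")
    msgs <- c(msgs,
      "the planted HindIII context requires cut base 'A' and uncut base 'T'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneratorConfig
#'
#' @param ampliconLength Product length in bp (default 550).
#' @param diagnosticPos 1-based amplicon position of the diagnostic SNP
#'   (default 248).
#' @param privatePos Position of the private SNP (default 169).
#' @param privateMajor,privateMinor Bases at the private SNP (defaults G / A).
#' @param privateCarrier Id of the single carrier individual (default
#'   "CD100").
#' @param flankLength Random flank on each side of the amplicon in templates
#'   (default 200).
#' @param errorRate Per-base substitution rate for emitted haplotypes
#'   (default 0).
#' @param seed Integer seed (default 1).
#' @param primers,enzyme Assay definition (defaults: EgSHP primers, HindIII).
#' @return A validated \linkS4class{GeneratorConfig}.
#' @export
generatorConfig <- function(ampliconLength = 550L, diagnosticPos = 248L,
                            privatePos = 169L, privateMajor = "G",
                            privateMinor = "A", privateCarrier = "CD100",
                            flankLength = 200L, errorRate = 0, seed = 1L,
                            primers = egSHPPrimers(), enzyme = hindIII()) {
  methods::new("GeneratorConfig",
    ampliconLength = as.integer(ampliconLength),
    diagnosticPos = as.integer(diagnosticPos),
    cutBase = "A", uncutBase = "T",
    privatePos = as.integer(privatePos),
    privateMajor = toupper(privateMajor), privateMinor = toupper(privateMinor),
    privateCarrier = as.character(privateCarrier),
    flankLength = as.integer(flankLength), errorRate = as.numeric(errorRate),
    seed = as.integer(seed), primers = primers, enzyme = enzyme)
}

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(
    "GeneratorConfig: %d bp amplicon, diagnostic SNP @%d (%s/%s), private SNP @%d (%s>%s, carrier %s)\n  flanks %d bp, error rate %g, seed %d\n",
    object@ampliconLength, object@diagnosticPos, object@cutBase,
    object@uncutBase, object@privatePos, object@privateMajor,
    object@privateMinor, object@privateCarrier, object@flankLength,
    object@errorRate, object@seed))
})

# protected amplicon intervals (matrix of start,end rows)
.protectedRegions <- function(cfg) {
  L <- cfg@ampliconLength
  fl <- nchar(cfg@primers@forward)
  rl <- nchar(cfg@primers@reverse)
  ctxStart <- cfg@diagnosticPos - .CTX_SNP_OFFSET + 1L
  rbind(c(1L, fl),
        c(ctxStart, ctxStart + nchar(.CTX_CUT) - 1L),
        c(cfg@privatePos, cfg@privatePos),
        c(L - rl + 1L, L))
}

.inRegions <- function(pos, regions) {
  any(pos >= regions[, 1L] & pos <= regions[, 2L])
}

# All disallowed feature matches in a sequence: enzyme sites and primer
# binding sites (either primer, either strand), except those whitelisted.
.spuriousHits <- function(seq, cfg, allowed) {
  hits <- list()
  ss <- scanSites(seq, cfg@enzyme)
  if (nrow(ss)) {
    hits$enz <- cbind(ss$position, ss$position + nchar(cfg@enzyme@site) - 1L)
  }
  for (p in c(cfg@primers@forward, cfg@primers@reverse)) {
    bs <- findBindingSites(seq, p, maxMismatch = 0L)
    if (nrow(bs)) {
      hits[[p]] <- cbind(bs$position, bs$position + nchar(p) - 1L)
    }
  }
  if (!length(hits)) return(matrix(integer(0), ncol = 2L))
  m <- do.call(rbind, hits)
  keep <- !apply(m, 1L, function(r) {
    any(allowed[, 1L] == r[1L] & allowed[, 2L] == r[2L])
  })
  m[keep, , drop = FALSE]
}

# Rewrite background bases until no spurious enzyme site or primer match
# remains in any of the sequences (which share background positions).
.scrubSet <- function(seqs, cfg, allowedList, protect) {
  for (iter in 1:200) {
    dirty <- FALSE
    for (k in seq_along(seqs)) {
      bad <- .spuriousHits(seqs[[k]], cfg, allowedList[[k]])
      if (!nrow(bad)) next
      dirty <- TRUE
      span <- bad[1L, 1L]:bad[1L, 2L]
      editable <- span[!vapply(span, .inRegions, logical(1), protect)]
      if (!length(editable)) {
        stop("cannot scrub a spurious match overlapping protected regions",
             call. = FALSE)
      }
      pos <- editable[sample.int(length(editable), 1L)]
      old <- substr(seqs[[k]], pos, pos)
      new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      # background positions are shared across the set
      for (j in seq_along(seqs)) substr(seqs[[j]], pos, pos) <- new
      break
    }
    if (!dirty) return(seqs)
  }
  stop("background scrubbing did not converge", call. = FALSE)
}

#' Build the cut and uncut amplicon alleles
#'
#' Equal-length sequences differing exactly at the diagnostic position; the
#' cut allele carries exactly one enzyme site (spanning the SNP), the uncut
#' allele none, and neither contains a spurious primer match. Both carry the
#' major base at the private position. Deterministic given the config seed.
#'
#' @param cfg A \linkS4class{GeneratorConfig}.
#' @return A named character vector \code{c(cut = ..., uncut = ...)}.
#' @export
makeAlleles <- function(cfg) {
  methods::validObject(cfg)
  .withSeed(.stageSeed(cfg@seed, "alleles"), {
    L <- cfg@ampliconLength
    chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    fwd <- .seqChars(cfg@primers@forward)
    rvc <- .seqChars(revComp(cfg@primers@reverse))
    chars[seq_along(fwd)] <- fwd
    chars[(L - length(rvc) + 1L):L] <- rvc
    ctxStart <- cfg@diagnosticPos - .CTX_SNP_OFFSET + 1L
    ctx <- .seqChars(.CTX_CUT)
    chars[ctxStart:(ctxStart + length(ctx) - 1L)] <- ctx
    chars[cfg@privatePos] <- cfg@privateMajor
    cut <- paste(chars, collapse = "")
    uncut <- cut
    substr(uncut, cfg@diagnosticPos, cfg@diagnosticPos) <- cfg@uncutBase

    fl <- length(fwd); rl <- length(rvc)
    sitePos <- cfg@diagnosticPos - 1L  # planted site starts one base left
    allowedCut <- rbind(c(1L, fl), c(L - rl + 1L, L),
                        c(sitePos, sitePos + nchar(cfg@enzyme@site) - 1L))
    allowedUncut <- rbind(c(1L, fl), c(L - rl + 1L, L))
    seqs <- .scrubSet(list(cut = cut, uncut = uncut), cfg,
                      list(allowedCut, allowedUncut),
                      protect = .protectedRegions(cfg))
    c(cut = seqs$cut, uncut = seqs$uncut)
  })
}

#' Wrap a haplotype in random flanks to form a PCR template
#'
#' The flanks are scrubbed so the template contains no primer match beyond
#' the planted pair: in-silico PCR returns exactly one amplicon.
#'
#' @param hap Amplicon-length haplotype sequence.
#' @param cfg A \linkS4class{GeneratorConfig}.
#' @param stage Substream label (vary per haplotype for distinct flanks).
#' @return Template string of length \code{flankLength*2 + nchar(hap)}.
#' @export
makeTemplate <- function(hap, cfg, stage = "template") {
  hap <- as.character(hap)
  if (cfg@flankLength == 0L) return(hap)
  .withSeed(.stageSeed(cfg@seed, stage), {
    fl <- cfg@flankLength
    L <- nchar(hap)
    repeat {
      left <- paste(sample(c("A", "C", "G", "T"), fl, TRUE), collapse = "")
      right <- paste(sample(c("A", "C", "G", "T"), fl, TRUE), collapse = "")
      tmpl <- paste0(left, hap, right)
      ok <- TRUE
      for (p in c(cfg@primers@forward, cfg@primers@reverse)) {
        bs <- findBindingSites(tmpl, p, maxMismatch = 0L)
        planted <- (p == cfg@primers@forward & bs$position == fl + 1L &
                      bs$strand == "+") |
                   (p == cfg@primers@reverse &
                      bs$position == fl + L - nchar(p) + 1L &
                      bs$strand == "-")
        if (any(!planted)) { ok <- FALSE; break }
      }
      if (ok) return(tmpl)
    }
  })
}

# seeded per-haplotype substitution errors, avoiding protected positions
.applyErrors <- function(hap, cfg, stage) {
  if (cfg@errorRate == 0) return(hap)
  .withSeed(.stageSeed(cfg@seed, stage), {
    chars <- .seqChars(hap)
    protect <- .protectedRegions(cfg)
    hit <- which(stats::runif(length(chars)) < cfg@errorRate)
    hit <- hit[!vapply(hit, .inRegions, logical(1), protect)]
    for (pos in hit) {
      chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1L)
    }
    paste(chars, collapse = "")
  })
}

#' Simulate progeny genotypes of a single-locus cross
#'
#' Each progeny draws one allele uniformly and independently from each
#' parent.
#'
#' @param p1,p2 Parent genotypes: length-2 character vectors over
#'   \code{c("cut", "uncut")}.
#' @param n Number of progeny (>= 1).
#' @param seed Integer seed.
#' @return An n x 2 character matrix of progeny allele pairs.
#' @export
simulateCross <- function(p1, p2, n, seed = 1L) {
  stopifnot(length(p1) == 2L, length(p2) == 2L,
            all(c(p1, p2) %in% c("cut", "uncut")))
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  .withSeed(seed, {
    cbind(p1[sample.int(2L, n, replace = TRUE)],
          p2[sample.int(2L, n, replace = TRUE)])
  })
}

.CROSS_PARENTS <- list(
  DxP = list(c("cut", "cut"), c("uncut", "uncut")),
  TxT = list(c("cut", "uncut"), c("cut", "uncut")))

.formFromGenotype <- function(g1, g2, model = shellMarkerModel()) {
  ncut <- (g1 == "cut") + (g2 == "cut")
  c(model@uncutLabel, model@hetLabel, model@cutLabel)[ncut + 1L]
}

#' Emit a complete synthetic cohort to disk
#'
#' Generates the allele pair, simulates the requested crosses, writes
#' amplicon-length haplotypes, flanked templates, a sample sheet and a truth
#' table, plus the resolved configuration. All files are plain text and parse
#' with the package readers; at error rate 0, re-calling genotypes from the
#' emitted files reproduces the truth table exactly.
#'
#' @param cfg A \linkS4class{GeneratorConfig}.
#' @param design data.frame with columns \code{cross} ("DxP" or "TxT") and
#'   \code{n}; default mirrors the validation cohorts (80 DxP + 60 TxT).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list: \code{files} (named paths), \code{truth},
#'   \code{samples} (data.frames), \code{alleles}, \code{haplotypes},
#'   \code{templates} (named character vectors).
#' @export
emitCohort <- function(cfg,
                       design = data.frame(cross = c("DxP", "TxT"),
                                           n = c(80L, 60L)),
                       dir = tempfile("cohort")) {
  stopifnot(all(c("cross", "n") %in% names(design)))
  bad <- setdiff(design$cross, names(.CROSS_PARENTS))
  if (length(bad)) {
    stop("unknown cross label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  alleles <- makeAlleles(cfg)

  samples <- list(); truth <- list()
  haps <- character(0); templates <- character(0)
  for (i in seq_len(nrow(design))) {
    cross <- design$cross[i]; n <- design$n[i]
    if (n == 0L) next
    parents <- .CROSS_PARENTS[[cross]]
    gt <- simulateCross(parents[[1L]], parents[[2L]], n,
                        seed = .stageSeed(cfg@seed, paste0("cross-", cross, i)))
    for (j in seq_len(n)) {
      sid <- sprintf("%s_%03d", cross, j)
      hid <- paste0(sid, c("_h1", "_h2"))
      for (k in 1:2) {
        hap <- .applyErrors(alleles[[gt[j, k]]], cfg,
                            stage = paste0("err-", hid[k]))
        haps[hid[k]] <- hap
        templates[hid[k]] <- makeTemplate(hap, cfg,
                                          stage = paste0("flank-", hid[k]))
      }
      samples[[length(samples) + 1L]] <- data.frame(
        sample_id = sid, hap1 = hid[1L], hap2 = hid[2L], cross = cross)
      truth[[length(truth) + 1L]] <- data.frame(
        sample_id = sid, allele1 = gt[j, 1L], allele2 = gt[j, 2L],
        true_form = .formFromGenotype(gt[j, 1L], gt[j, 2L]))
    }
  }
  emptyS <- data.frame(sample_id = character(0), hap1 = character(0),
                       hap2 = character(0), cross = character(0))
  emptyT <- data.frame(sample_id = character(0), allele1 = character(0),
                       allele2 = character(0), true_form = character(0))
  samples <- if (length(samples)) do.call(rbind, samples) else emptyS
  truth <- if (length(truth)) do.call(rbind, truth) else emptyT

  files <- c(haplotypes = file.path(dir, "haplotypes.fa"),
             templates = file.path(dir, "templates.fa"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.yaml"))
  writeFasta(Biostrings::DNAStringSet(haps), files[["haplotypes"]])
  writeFasta(Biostrings::DNAStringSet(templates), files[["templates"]])
  .writeTsv(samples, files[["samples"]])
  .writeTsv(truth, files[["truth"]])
  yaml::write_yaml(configAsList(cfg), files[["config"]])
  invisible(list(files = files, truth = truth, samples = samples,
                 alleles = alleles, haplotypes = haps, templates = templates))
}

#' Serialise a GeneratorConfig to a plain list (for YAML round-trips)
#' @param cfg A \linkS4class{GeneratorConfig}.
#' @return A named list.
#' @export
configAsList <- function(cfg) {
  list(amplicon_length = cfg@ampliconLength,
       diagnostic_pos = cfg@diagnosticPos,
       private_pos = cfg@privatePos,
       private_major = cfg@privateMajor, private_minor = cfg@privateMinor,
       private_carrier = cfg@privateCarrier,
       flank_length = cfg@flankLength, error_rate = cfg@errorRate,
       seed = cfg@seed,
       forward_primer = cfg@primers@forward,
       reverse_primer = cfg@primers@reverse,
       enzyme = list(name = cfg@enzyme@name, site = cfg@enzyme@site,
                     cut_top = cfg@enzyme@cutTop,
                     cut_bottom = cfg@enzyme@cutBottom))
}

#' Rebuild a GeneratorConfig from its serialised list
#' @param x A list as produced by [configAsList()] (unknown keys ignored).
#' @return A \linkS4class{GeneratorConfig}.
#' @export
configFromList <- function(x) {
  defaults <- configAsList(generatorConfig())
  for (k in names(defaults)) if (is.null(x[[k]])) x[[k]] <- defaults[[k]]
  generatorConfig(
    ampliconLength = x$amplicon_length, diagnosticPos = x$diagnostic_pos,
    privatePos = x$private_pos, privateMajor = x$private_major,
    privateMinor = x$private_minor, privateCarrier = x$private_carrier,
    flankLength = x$flank_length, errorRate = x$error_rate, seed = x$seed,
    primers = PrimerPair("assay", x$forward_primer, x$reverse_primer),
    enzyme = RestrictionEnzyme(x$enzyme$name, x$enzyme$site,
                               x$enzyme$cut_top, x$enzyme$cut_bottom))
}

#' Build a group-labelled haplotype panel alignment
#'
#' Emulates a sequenced reference panel: cut-allele haplotypes labelled with
#' the cut-homozygote group (the first one, named after the configured
#' carrier, bears the private minor allele), uncut haplotypes labelled with
#' the uncut-homozygote group, and heterozygote-derived haplotypes
#' alternating between the two alleles. Rows are equal-length and gap-free,
#' so the set is its own alignment.
#'
#' @param cfg A \linkS4class{GeneratorConfig}.
#' @param nDura,nPisifera,nTenera Row counts per group (defaults 3/3/6,
#'   mirroring a twelve-sequence panel).
#' @return A \linkS4class{GroupedAlignment}.
#' @export
makePanel <- function(cfg, nDura = 3L, nPisifera = 3L, nTenera = 6L) {
  stopifnot(nDura >= 1L, nPisifera >= 1L)
  alleles <- makeAlleles(cfg)
  ids_d <- c(cfg@privateCarrier,
             if (nDura > 1L) sprintf("D%02d", seq_len(nDura - 1L)))
  ids_p <- sprintf("P%02d", seq_len(nPisifera))
  ids_t <- if (nTenera > 0L) sprintf("T%02d", seq_len(nTenera)) else character(0)
  seqs <- c(
    setNames(rep(alleles[["cut"]], nDura), ids_d),
    setNames(rep(alleles[["uncut"]], nPisifera), ids_p),
    setNames(rep(c(alleles[["cut"]], alleles[["uncut"]]),
                 length.out = nTenera), ids_t))
  substr(seqs[[1L]], cfg@privatePos, cfg@privatePos) <- cfg@privateMinor
  if (cfg@errorRate > 0) {
    seqs <- setNames(vapply(names(seqs), function(id)
      .applyErrors(seqs[[id]], cfg, paste0("panel-err-", id)),
      character(1)), names(seqs))
  }
  groups <- setNames(rep(c("dura", "pisifera", "tenera"),
                         c(nDura, nPisifera, nTenera)), names(seqs))
  GroupedAlignment(Biostrings::DNAStringSet(seqs), groups = groups)
}

# deterministic TSV writer shared by generator and pipeline
.writeTsv <- function(df, path) {
  flat <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
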