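# End-to-end orchestration: simulate -> pcr -> mine-ssrs -> discover-snps ->
# design-caps -> genotype -> (optional) associate, with a file manifest and a
# serialised resolved configuration for byte-identical re-runs.

.defaultRunConfig <- function() {
  list(
    seed = 1L,
    out_dir = "caps_run",
    generator = configAsList(generatorConfig()),
    design = list(list(cross = "DxP", n = 80L), list(cross = "TxT", n = 60L)),
    enzymes = NULL,          # NULL -> shipped table
    marker = list(tolerance = 15),
    panel = list(n_dura = 3L, n_pisifera = 3L, n_tenera = 6L),
    caps = list(window = 30L, min_fragment = 80L, min_separation = 30L),
    traits = NULL,           # optional TSV path
    covariates = NULL        # optional TSV path
  )
}

# merge user config over defaults (shallow for stage blocks)
.mergeConfig <- function(user) {
  cfg <- .defaultRunConfig()
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]]) && k != "design") {
      for (kk in names(user[[k]])) cfg[[k]][[kk]] <- user[[k]][[kk]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

# validate the resolved config; all violations reported at once
.validateRunConfig <- function(cfg) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L,
      "seed: must be a single integer")
  chk(is.character(cfg$out_dir) && nzchar(cfg$out_dir),
      "out_dir: must be a non-empty path")
  for (d in cfg$design) {
    chk(!is.null(d$cross) && d$cross %in% c("DxP", "TxT"),
        sprintf("design: unknown cross '%s'", d$cross %||% "<missing>"))
    chk(!is.null(d$n) && is.numeric(d$n) && d$n >= 0,
        "design: each entry needs n >= 0")
  }
  if (!is.null(cfg$enzymes)) {
    chk(file.exists(cfg$enzymes),
        sprintf("enzymes: file not found '%s'", cfg$enzymes))
  }
  chk(is.numeric(cfg$marker$tolerance) && cfg$marker$tolerance >= 0,
      "marker.tolerance: must be >= 0")
  er <- cfg$generator$error_rate
  chk(is.numeric(er) && er >= 0 && er <= 1,
      "generator.error_rate: must be in [0, 1]")
  for (f in c("traits", "covariates")) {
    if (!is.null(cfg[[f]])) {
      chk(file.exists(cfg[[f]]), sprintf("%s: file not found '%s'", f,
                                         cfg[[f]]))
    }
  }
  if (length(errs)) {
    stop("invalid run configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full CAPS-marker pipeline
#'
#' Stages: synthetic-cohort simulation, in-silico PCR of every template, SSR
#' mining, variant discovery/classification on the reference panel, CAPS
#' candidate design, cohort genotyping with segregation tests, and (when a
#' trait table is configured) a single-marker association scan. Every stage's
#' outputs are written under \code{out_dir} and listed in a manifest with MD5
#' checksums; the resolved configuration is serialised alongside, and
#' re-running from it reproduces all tabular outputs byte for byte. Progress
#' is logged to standard error; a stage failure halts with a stage-named
#' error.
#'
#' @param config A named list, or path to a YAML file, overriding the
#'   defaults (seeded 80 DxP + 60 TxT demo cohort).
#' @param outDir Overrides \code{config$out_dir}.
#' @return Invisibly, a list: \code{manifest} (data.frame), \code{calls},
#'   \code{segregation}, \code{variants}, \code{candidates},
#'   \code{accuracy} (fraction of calls matching the simulated truth), and
#'   \code{config} (resolved).
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- .validateRunConfig(.mergeConfig(config))
  if (!is.null(outDir)) cfg$out_dir <- outDir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  stageFail <- function(stage, e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }
  runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e) stageFail(stage, e))
  }
  manifest <- list()
  record <- function(stage, path) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(path),
      md5 = unname(tools::md5sum(path)))
  }

  gen <- configFromList(cfg$generator)
  gen@seed <- as.integer(cfg$seed)
  design <- do.call(rbind, lapply(cfg$design, function(d)
    data.frame(cross = d$cross, n = as.integer(d$n))))
  enzymes <- readEnzymeTable(cfg$enzymes %||% defaultEnzymeFile())
  model <- MarkerModel(gen@primers, gen@enzyme,
                       ampliconLength = gen@ampliconLength,
                       tolerance = cfg$marker$tolerance)

  log("simulate", "emitting cohort (%s) with seed %d",
      paste(sprintf("%s n=%d", design$cross, design$n), collapse = ", "),
      gen@seed)
  sim <- runStage("simulate", emitCohort(gen, design, dir = cfg$out_dir))
  for (f in sim$files) record("simulate", f)

  log("pcr", "amplifying %d templates", length(sim$templates))
  amp <- runStage("pcr", amplify(sim$templates, gen@primers))
  ampFa <- file.path(cfg$out_dir, "amplicons.fa")
  runStage("pcr", {
    if (nrow(amp) != length(sim$templates)) {
      stop(sprintf("%d templates but %d products", length(sim$templates),
                   nrow(amp)))
    }
    writeFasta(setNames(amp$seq, amp$template_id), ampFa)
  })
  record("pcr", ampFa)

  log("mine-ssrs", "scanning %d sequences", length(sim$templates))
  ssrs <- runStage("mine-ssrs", mineSSRs(sim$templates))
  ssrFile <- file.path(cfg$out_dir, "ssrs.tsv")
  .writeTsv(ssrs, ssrFile); record("mine-ssrs", ssrFile)

  log("discover-snps", "panel %d/%d/%d dura/pisifera/tenera",
      cfg$panel$n_dura, cfg$panel$n_pisifera, cfg$panel$n_tenera)
  panel <- runStage("discover-snps",
    makePanel(gen, cfg$panel$n_dura, cfg$panel$n_pisifera,
              cfg$panel$n_tenera))
  variants <- runStage("discover-snps", callVariants(panel))
  panelFa <- file.path(cfg$out_dir, "panel.fa")
  writeFasta(alnSeqs(panel), panelFa); record("discover-snps", panelFa)
  varFile <- file.path(cfg$out_dir, "variants.tsv")
  .writeTsv(variants, varFile); record("discover-snps", varFile)

  log("design-caps", "screening %d enzymes", length(enzymes))
  cands <- runStage("design-caps", rankCandidates(
    findCapsCandidates(sim$alleles[["cut"]], sim$alleles[["uncut"]],
                       enzymes, window = cfg$caps$window),
    minFragment = cfg$caps$min_fragment,
    minSeparation = cfg$caps$min_separation))
  candFile <- file.path(cfg$out_dir, "candidates.tsv")
  .writeTsv(cands, candFile); record("design-caps", candFile)

  log("genotype", "screening %d samples", nrow(sim$samples))
  seg <- list(); callRows <- list()
  for (cr in unique(sim$samples$cross)) {
    sub <- sim$samples[sim$samples$cross == cr, , drop = FALSE]
    res <- runStage("genotype",
      screenCohort(sim$templates, sub, model, cross = cr))
    callRows[[cr]] <- cbind(cohortCalls(res), cross = cr)
    seg[[cr]] <- segregationTest(res)
  }
  calls <- if (length(callRows)) do.call(rbind, callRows) else
    data.frame(sample_id = character(0), call = character(0),
               bands = character(0), cross = character(0))
  segregation <- if (length(seg)) do.call(rbind, seg) else
    data.frame(cross = character(0), n = integer(0), chisq = numeric(0),
               df = integer(0), p_value = numeric(0),
               n_contamination = integer(0))
  rownames(calls) <- rownames(segregation) <- NULL
  callFile <- file.path(cfg$out_dir, "calls.tsv")
  segFile <- file.path(cfg$out_dir, "segregation.tsv")
  .writeTsv(calls, callFile); record("genotype", callFile)
  .writeTsv(segregation, segFile); record("genotype", segFile)
  accuracy <- if (nrow(calls)) {
    mean(calls$call[match(sim$truth$sample_id, calls$sample_id)] ==
           sim$truth$true_form)
  } else NA_real_
  if (!is.na(accuracy)) log("genotype", "truth agreement %.1f%%",
                            100 * accuracy)

  assoc <- NULL
  if (!is.null(cfg$traits)) {
    log("associate", "scanning traits from %s", cfg$traits)
    traits <- utils::read.delim(cfg$traits, check.names = FALSE)
    covs <- if (!is.null(cfg$covariates)) {
      utils::read.delim(cfg$covariates, check.names = FALSE)
    }
    markerDf <- data.frame(sample_id = calls$sample_id, CAPS = calls$call)
    assoc <- runStage("associate", scanMarkers(traits, markerDf, covs))
    assocFile <- file.path(cfg$out_dir, "associations.tsv")
    .writeTsv(assoc, assocFile); record("associate", assocFile)
  } else {
    log("associate", "no trait table configured; stage skipped")
  }

  resolved <- file.path(cfg$out_dir, "config_resolved.yaml")
  cfgOut <- cfg
  cfgOut$generator <- configAsList(gen)
  yaml::write_yaml(cfgOut, resolved)
  record("config", resolved)

  manifest <- do.call(rbind, manifest)
  manFile <- file.path(cfg$out_dir, "manifest.tsv")
  .writeTsv(manifest, manFile)
  log("done", "%d files in %s", nrow(manifest), cfg$out_dir)
  invisible(list(manifest = manifest, calls = calls,
                 segregation = segregation, variants = variants,
                 candidates = cands, ssrs = ssrs, association = assoc,
                 accuracy = accuracy, config = cfgOut))
}
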