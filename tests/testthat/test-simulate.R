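test_that("generated alleles carry the planted structure and nothing else", {
  cfg <- generatorConfig(seed = 31L)
  al <- makeAlleles(cfg)
  expect_identical(unname(nchar(al)), c(550L, 550L))
  diffs <- which(strsplit(al[["cut"]], "")[[1]] !=
                 strsplit(al[["uncut"]], "")[[1]])
  expect_identical(diffs, 248L)       # alleles differ only at the SNP
  # the 21-mer centred on the codon block equals the printed contexts
  expect_identical(substr(al[["cut"]], 234, 254), CTX_DURA)
  expect_identical(substr(al[["uncut"]], 234, 254), CTX_PISIFERA)
  # exactly one HindIII site on the cut allele, spanning the SNP; none uncut
  sc <- scanSites(al[["cut"]], hindIII())
  expect_identical(nrow(sc), 1L)
  expect_identical(sc$position, 247L)
  expect_identical(nrow(scanSites(al[["uncut"]], hindIII())), 0L)
  # both carry the private-major base; primers bracket the product
  expect_identical(substr(al[["cut"]], 169, 169), "G")
  expect_true(startsWith(al[["cut"]], egSHPPrimers()@forward))
  expect_true(endsWith(al[["cut"]], revComp(egSHPPrimers()@reverse)))
})

test_that("allele generation is deterministic in the seed", {
  cfg <- generatorConfig(seed = 8L)
  expect_identical(makeAlleles(cfg), makeAlleles(cfg))
  expect_false(identical(makeAlleles(cfg),
                         makeAlleles(generatorConfig(seed = 9L))))
})

test_that("infeasible SNP placement is a configuration error", {
  expect_error(generatorConfig(diagnosticPos = 10L), "infeasible")
  expect_error(generatorConfig(privatePos = 5L), "private_pos")
})

test_that("templates amplify to exactly one product of the configured length", {
  cfg <- generatorConfig(seed = 32L)
  al <- makeAlleles(cfg)
  for (hap in al) {
    tmpl <- makeTemplate(hap, cfg, stage = paste0("t-", substr(hap, 1, 4)))
    expect_identical(nchar(tmpl), 950L)
    amp <- amplify(tmpl, cfg@primers)
    expect_identical(nrow(amp), 1L)
    expect_identical(amp$length, 550L)
    expect_identical(amp$seq, hap)
  }
  # zero flank: the amplicon is the whole template
  cfg0 <- generatorConfig(seed = 32L, flankLength = 0L)
  expect_identical(makeTemplate(al[["cut"]], cfg0), al[["cut"]])
})

test_that("haplotype errors are seeded, reproducible and spare primer sites", {
  cfg <- generatorConfig(seed = 33L, errorRate = 0.01)
  al <- makeAlleles(cfg)
  m1 <- capsScreen:::.applyErrors(al[["cut"]], cfg, "err-x")
  m2 <- capsScreen:::.applyErrors(al[["cut"]], cfg, "err-x")
  expect_identical(m1, m2)
  expect_false(identical(m1, capsScreen:::.applyErrors(al[["cut"]], cfg,
                                                       "err-y")))
  expect_true(startsWith(m1, cfg@primers@forward))
  expect_true(endsWith(m1, revComp(cfg@primers@reverse)))
})

test_that("cross simulation follows Mendelian draws", {
  # D x P is forced heterozygosity
  gt <- simulateCross(c("cut", "cut"), c("uncut", "uncut"), 50, seed = 1)
  expect_true(all(gt[, 1] == "cut" & gt[, 2] == "uncut"))
  # same seed, same progeny
  expect_identical(simulateCross(c("cut", "uncut"), c("cut", "uncut"), 100, 3),
                   simulateCross(c("cut", "uncut"), c("cut", "uncut"), 100, 3))
  expect_error(simulateCross(c("cut", "cut"), c("cut", "cut"), 0), ">= 1")
  # T x T class fractions within 3 standard errors of (1/4, 1/2, 1/4)
  gt <- simulateCross(c("cut", "uncut"), c("cut", "uncut"), 10000, seed = 1)
  ncut <- rowSums(gt == "cut")
  frac <- as.numeric(table(factor(ncut, levels = 2:0))) / 10000
  se <- sqrt(c(.25, .5, .25) * c(.75, .5, .75) / 10000)
  expect_true(all(abs(frac - c(.25, .5, .25)) <= 3 * se))
})

test_that("emitCohort writes a parseable, truth-consistent cohort", {
  cfg <- generatorConfig(seed = 34L)
  dir <- withr::local_tempdir()
  out <- emitCohort(cfg, data.frame(cross = c("DxP", "TxT"), n = c(8L, 6L)),
                    dir = dir)
  expect_identical(nrow(out$samples), 14L)
  expect_identical(length(out$haplotypes), 28L)   # two haplotypes per sample
  haps <- readFasta(out$files[["haplotypes"]])
  expect_identical(length(haps), 28L)
  expect_identical(unname(as.character(haps)), unname(out$haplotypes))
  # re-calling genotypes from the emitted files reproduces the truth table
  samples <- read.delim(out$files[["samples"]])
  truth <- read.delim(out$files[["truth"]])
  tmpl <- readFasta(out$files[["templates"]])
  model <- shellMarkerModel()
  for (cr in c("DxP", "TxT")) {
    sub <- samples[samples$cross == cr, ]
    res <- screenCohort(tmpl, sub, model, cross = cr)
    calls <- cohortCalls(res)
    expect_identical(calls$call,
                     truth$true_form[match(calls$sample_id, truth$sample_id)])
  }
  # DxP progeny are all heterozygous by design
  expect_true(all(truth$true_form[truth$sample_id %in%
                                    samples$sample_id[samples$cross == "DxP"]]
                  == "tenera"))
})

test_that("an empty design emits valid empty outputs", {
  cfg <- generatorConfig(seed = 35L)
  dir <- withr::local_tempdir()
  out <- emitCohort(cfg, data.frame(cross = character(0), n = integer(0)),
                    dir = dir)
  expect_identical(nrow(out$samples), 0L)
  expect_true(file.exists(out$files[["samples"]]))
  expect_identical(nrow(read.delim(out$files[["samples"]])), 0L)
})

test_that("panel alignments plant exactly one diagnostic and one private column", {
  for (seed in c(41L, 42L, 43L)) {
    cfg <- generatorConfig(seed = seed)
    panel <- makePanel(cfg)
    expect_identical(length(panel), 12L)
    vt <- callVariants(panel)
    expect_identical(nrow(vt), 2L)
    expect_identical(vt$column, c(169L, 248L))
    expect_identical(vt$classification, c("private", "diagnostic"))
    expect_identical(vt$carrier[1], "CD100")
    expect_identical(vt$ti_tv, c("transition", "transversion"))
  }
})
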