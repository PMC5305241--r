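test_that("digestion cuts at site_start - 1 + cutTop and conserves length", {
  al <- makeAlleles(generatorConfig(seed = 1L))
  # planted site starts at 247, HindIII cuts after one base: 247 | 303
  expect_identical(digestSeq(al[["cut"]], hindIII()), c(247L, 303L))
  expect_identical(digestSeq(al[["uncut"]], hindIII()), 550L)
})

test_that("fragment lengths always sum to the sequence length", {
  set.seed(14)
  enzymes <- readEnzymeTable()
  for (i in 1:15) {
    s <- randomSeq(sample(30:600, 1))
    for (enz in enzymes) {
      expect_identical(sum(digestSeq(s, enz)), nchar(s),
                       label = enzymeName(enz))
    }
  }
})

test_that("type-IIS enzymes cut downstream of their recognition site", {
  mboII <- RestrictionEnzyme("MboII", "GAAGA", 13, 12)
  s <- paste0(strrep("C", 10), "GAAGA", strrep("T", 20))   # site at 11
  expect_identical(digestSeq(s, mboII), c(23L, 12L))       # cut after 10+13
  # a cut falling beyond the end is dropped, not an error
  near_end <- paste0(strrep("C", 10), "GAAGA", "TT")
  expect_identical(digestSeq(near_end, mboII), 17L)
})

test_that("diploid band patterns merge within tolerance, longest member represents", {
  p <- diploidBandPattern(c(280, 270), 550, tolerance = 15)
  expect_identical(bands(p), c(550, 280))        # 280/270 co-migrate
  p5 <- diploidBandPattern(c(280, 270), 550, tolerance = 5)
  expect_identical(bands(p5), c(550, 280, 270))  # resolved at tighter gel
  hom <- diploidBandPattern(550, 550, tolerance = 15)
  expect_identical(bands(hom), 550)
  same <- diploidBandPattern(c(280, 270), c(280, 270), tolerance = 5)
  expect_identical(bands(same), c(280, 270))     # homozygote = one haplotype
  expect_error(diploidBandPattern(numeric(0), 550), "at least one fragment")
})

test_that("band merging is single-linkage (chains collapse)", {
  p <- diploidBandPattern(c(100, 112), c(124, 300), tolerance = 15)
  expect_identical(bands(p), c(300, 124))
  expect_identical(p@members[[2]], c(100, 112, 124))
})

test_that("fruit-form calls follow the band-count model", {
  model <- shellMarkerModel()
  expect_identical(
    callFruitForm(diploidBandPattern(550, 550, 15), model), "pisifera")
  expect_identical(
    callFruitForm(diploidBandPattern(c(247, 303), c(247, 303), 15), model),
    "dura")
  expect_identical(
    callFruitForm(diploidBandPattern(c(247, 303), 550, 15), model), "tenera")
  expect_identical(
    callFruitForm(diploidBandPattern(c(300, 150), 100, 15), model),
    "unresolved")
})

test_that("heterozygote pattern is the merged union of the homozygote patterns", {
  set.seed(15)
  for (i in 1:10) {
    fa <- sort(sample(50:600, sample(1:4, 1)))
    fb <- sort(sample(50:600, sample(1:4, 1)))
    het <- bands(diploidBandPattern(fa, fb, 15))
    unionP <- bands(diploidBandPattern(c(fa, fa), c(fb, fb), 15))
    expect_identical(het, unionP)
  }
})

test_that("screenCohort computes the 1:2:1 chi-square as the textbook formula", {
  cfg <- generatorConfig(seed = 21L)
  al <- makeAlleles(cfg)
  haps <- c(cutH = al[["cut"]], uncutH = al[["uncut"]])
  model <- shellMarkerModel()
  mkSamples <- function(nCut, nHet, nUncut) {
    data.frame(
      sample_id = sprintf("s%03d", seq_len(nCut + nHet + nUncut)),
      hap1 = c(rep("cutH", nCut), rep("cutH", nHet), rep("uncutH", nUncut)),
      hap2 = c(rep("cutH", nCut), rep("uncutH", nHet), rep("uncutH", nUncut)))
  }
  # perfect 15/30/15 fit: statistic 0, p = 1
  res <- screenCohort(haps, mkSamples(15, 30, 15), model, cross = "TxT",
                      amplified = TRUE)
  expect_identical(res@chisq, 0)
  expect_identical(res@pValue, 1)
  expect_identical(res@df, 2L)
  # 50/50/0: (50-25)^2/25 + (50-50)^2/50 + (0-25)^2/25 = 50
  res <- screenCohort(haps, mkSamples(50, 50, 0), model, cross = "TxT",
                      amplified = TRUE)
  expect_identical(res@chisq, 50)
  expect_identical(res@df, 2L)
  expect_equal(res@pValue, pchisq(50, 2, lower.tail = FALSE))
})

test_that("DxP screening flags every non-heterozygote as contamination", {
  cfg <- generatorConfig(seed = 22L)
  al <- makeAlleles(cfg)
  haps <- c(cutH = al[["cut"]], uncutH = al[["uncut"]])
  model <- shellMarkerModel()
  samples <- data.frame(sample_id = c("ok1", "ok2", "bad"),
                        hap1 = c("cutH", "cutH", "cutH"),
                        hap2 = c("uncutH", "uncutH", "cutH"))
  res <- screenCohort(haps, samples, model, cross = "DxP", amplified = TRUE)
  expect_identical(res@contamination, "bad")
  expect_identical(res@pValue, 0)   # an off-class call breaks the all-het model
  clean <- screenCohort(haps, samples[1:2, ], model, cross = "DxP",
                        amplified = TRUE)
  expect_identical(length(clean@contamination), 0L)
  expect_identical(clean@pValue, 1)
  expect_identical(clean@df, 0L)
})

test_that("unknown cross labels are configuration errors", {
  expect_error(
    screenCohort(c(h = "ACGT"), data.frame(sample_id = "s", hap1 = "h",
                                           hap2 = "h"),
                 shellMarkerModel(), cross = "DxT"),
    "unknown cross")
})
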