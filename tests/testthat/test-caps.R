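test_that("HindIII scanning matches the printed codon contexts", {
  hits <- scanSites(CTX_DURA, hindIII())
  expect_identical(hits$position, 14L)
  expect_identical(hits$strand, "+")
  expect_identical(nrow(scanSites(CTX_PISIFERA, hindIII())), 0L)
})

test_that("degenerate sites and both-strand scanning work", {
  enz <- RestrictionEnzyme("toy", "GGNNCC", 3, 3)
  expect_identical(scanSites("AAGGTACCAA", enz)$position, 3L)
  # non-palindromic site found on the minus strand in top-strand coordinates
  mboII <- RestrictionEnzyme("MboII", "GAAGA", 13, 12)
  hits <- scanSites(paste0("CCC", revComp("GAAGA"), "CCC"), mboII)
  expect_identical(hits$position, 4L)
  expect_identical(hits$strand, "-")
})

test_that("site scanning equals the brute-force IUPAC oracle for every shipped enzyme", {
  enzymes <- readEnzymeTable()
  expect_setequal(names(enzymes),
                  c("HindIII", "BseMII", "MboII", "EcoP15I", "NaeI"))
  set.seed(13)
  for (i in 1:12) {
    s <- randomSeq(sample(50:500, 1))
    for (enz in enzymes) {
      got <- scanSites(s, enz)
      plus <- oracleScanPlus(s, enzymeSite(enz))
      minus <- if (enzymeSite(enz) != revComp(enzymeSite(enz))) {
        oracleScanPlus(s, revComp(enzymeSite(enz)))
      } else integer(0)
      expect_identical(got$position[got$strand == "+"], plus,
                       label = paste(enzymeName(enz), "plus"))
      expect_identical(got$position[got$strand == "-"], minus,
                       label = paste(enzymeName(enz), "minus"))
    }
  }
})

test_that("the synthetic allele pair nominates HindIII with the site destroyed", {
  al <- makeAlleles(generatorConfig(seed = 99L))
  cands <- findCapsCandidates(al[["cut"]], al[["uncut"]])
  expect_true("HindIII" %in% cands$enzyme)
  hind <- cands[cands$enzyme == "HindIII", ]
  expect_identical(hind$differential, "destroyed")  # A-allele -> T-allele
  expect_identical(hind$variant_pos, 248L)
  expect_identical(sort(hind$fragments_A[[1]]), c(247L, 303L))
  expect_identical(hind$fragments_B[[1]], 550L)
})

test_that("variants away from any site, or shared sites, yield no candidate", {
  a <- paste0(strrep("ACGGT", 20), "A", strrep("GCCAT", 20))
  b <- paste0(strrep("ACGGT", 20), "T", strrep("GCCAT", 20))
  expect_identical(nrow(findCapsCandidates(a, b, list(hindIII()))), 0L)
  # identical site sets (site far from the variant) are excluded too
  a2 <- paste0("AAGCTT", strrep("C", 60), "A", strrep("G", 40))
  b2 <- paste0("AAGCTT", strrep("C", 60), "T", strrep("G", 40))
  expect_identical(nrow(findCapsCandidates(a2, b2, list(hindIII()))), 0L)
})

test_that("identical alleles are a precondition error", {
  expect_error(findCapsCandidates("ACGTACGT", "ACGTACGT"), "identical")
})

test_that("candidate discovery is symmetric up to created/destroyed relabelling", {
  al <- makeAlleles(generatorConfig(seed = 5L))
  fwd <- findCapsCandidates(al[["cut"]], al[["uncut"]])
  rev <- findCapsCandidates(al[["uncut"]], al[["cut"]])
  expect_identical(fwd$enzyme, rev$enzyme)
  swap <- c(destroyed = "created", created = "destroyed")
  expect_identical(unname(swap[fwd$differential]), rev$differential)
  expect_identical(fwd$fragments_A, rev$fragments_B)
})

test_that("ranking retains gel-practical candidates and demotes the rest", {
  mk <- function(enzyme, fragsA, fragsB, sep, minf) {
    row <- data.frame(enzyme = enzyme, site = "NNNN", variant_pos = 1L,
                      site_pos = 1L, differential = "destroyed",
                      n_sites_A = 1L, n_sites_B = 0L,
                      min_fragment = minf, separation = sep)
    row$sites_A <- list(1L); row$sites_B <- list(integer(0))
    row$fragments_A <- list(fragsA); row$fragments_B <- list(fragsB)
    row
  }
  good <- mk("GoodZ", c(280, 270), 550, sep = 270, minf = 270)
  tiny <- mk("Tiny", c(538, 12), 550, sep = 12, minf = 12)
  ranked <- rankCandidates(rbind(tiny, good))
  expect_identical(ranked$enzyme, c("GoodZ", "Tiny"))
  expect_identical(ranked$retained, c(TRUE, FALSE))
  # singleton retained candidate ranks first trivially
  one <- rankCandidates(good)
  expect_true(one$retained)
  # empty in, empty out
  empty <- findCapsCandidates("AAAA", "AAAT", list())
  expect_identical(nrow(rankCandidates(empty)), 0L)
})
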