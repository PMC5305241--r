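test_that("identical sequences yield no variant columns", {
  aln <- toyAlignment(c(a = "ACGTACGT", b = "ACGTACGT"),
                      c(a = "dura", b = "pisifera"))
  expect_identical(nrow(findVariantColumns(aln)), 0L)
})

test_that("a single-sequence alignment is a precondition error", {
  aln <- toyAlignment(c(a = "ACGT"), c(a = "dura"))
  expect_error(findVariantColumns(aln), "at least two")
})

test_that("gap-only differences are not variants; degapped offsets track gaps", {
  aln <- toyAlignment(c(a = "AC-TA", b = "ACGTA", c = "AC-TT"),
                      c(a = "dura", b = "dura", c = "pisifera"))
  vc <- findVariantColumns(aln)
  expect_identical(vc$column, 5L)          # column 3 is {A,-,A}: no variant
  expect_identical(vc$bases, "A/T")
  # degapped offsets: column 5 is base 4 of the gapped rows, base 5 of row b
  expect_identical(vc$degapped[[1]], c(a = 4L, b = 5L, c = 4L))
})

test_that("classification follows the diagnostic / private / uninformative rules", {
  groups <- c(d1 = "dura", d2 = "dura", p1 = "pisifera", p2 = "pisifera",
              t1 = "tenera", t2 = "tenera")
  # dura fixed A, pisifera fixed T, tenera mixed -> diagnostic
  cls <- classifyColumn(c(d1 = "A", d2 = "A", p1 = "T", p2 = "T",
                          t1 = "A", t2 = "T"), groups)
  expect_identical(cls$classification, "diagnostic")
  # one dura carries the minor allele -> private, carrier attributed
  cls <- classifyColumn(c(d1 = "G", d2 = "A", p1 = "G", p2 = "G",
                          t1 = "G", t2 = "G"), groups)
  expect_identical(cls$classification, "private")
  expect_identical(cls$carrier, "d2")
  # no fixation, both alleles shared -> uninformative
  cls <- classifyColumn(c(d1 = "A", d2 = "T", p1 = "A", p2 = "T",
                          t1 = "A", t2 = "T"), groups)
  expect_identical(cls$classification, "uninformative")
  # empty reference group is a configuration error
  expect_error(
    classifyColumn(c(d1 = "A", d2 = "T"), c(d1 = "dura", d2 = "dura")),
    "pisifera")
})

test_that("classification agrees with brute-force enumeration on small panels", {
  # brute force: re-state the rules over every allele assignment
  oracleClassify <- function(alleles, groups) {
    refs <- lapply(c("dura", "pisifera"), function(g)
      unique(alleles[names(groups)[groups == g]]))
    if (length(refs[[1]]) == 1 && length(refs[[2]]) == 1 &&
        refs[[1]] != refs[[2]]) return("diagnostic")
    tab <- table(alleles)
    if (length(tab) == 2 && min(tab) == 1) return("private")
    "uninformative"
  }
  groups <- c(a = "dura", b = "dura", c = "pisifera", d = "pisifera",
              e = "tenera")
  combos <- expand.grid(rep(list(c("A", "T", "G")), 5),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    alleles <- setNames(unlist(combos[i, ]), names(groups))
    expect_identical(
      classifyColumn(alleles, groups)$classification,
      oracleClassify(alleles, groups),
      label = paste(alleles, collapse = ""))
  }
})

test_that("diagnostic classification is symmetric in the two reference groups", {
  groups <- c(d1 = "dura", d2 = "dura", p1 = "pisifera", t1 = "tenera")
  alleles <- c(d1 = "A", d2 = "A", p1 = "T", t1 = "A")
  for (refs in list(c("dura", "pisifera"), c("pisifera", "dura"))) {
    expect_identical(classifyColumn(alleles, groups, refs)$classification,
                     "diagnostic")
  }
})

test_that("transitions and transversions follow the standard definition", {
  expect_identical(mutationType("G", "A"), "transition")
  expect_identical(mutationType("C", "T"), "transition")
  # A<->T is a transversion by the purine/pyrimidine rule
  expect_identical(mutationType("A", "T"), "transversion")
  expect_identical(mutationType("G", "C"), "transversion")
  expect_true(is.na(mutationType("N", "A")))
  expect_error(mutationType("A", "A"), "differ")
})

test_that("codon effects reproduce the SHELL K-to-N substitution", {
  eff <- annotateEffect(CTX_DURA, 15, "T")
  expect_identical(eff$codon_ref, "AAA")
  expect_identical(eff$codon_alt, "AAT")
  expect_identical(eff$aa_ref, "K")
  expect_identical(eff$aa_alt, "N")
  expect_false(eff$synonymous)
})

test_that("codon effects respect frames, synonymy and partial-codon errors", {
  # AGA arginine: second base G->C gives ACA threonine
  eff <- annotateEffect("AGA", 2, "C")
  expect_identical(c(eff$aa_ref, eff$aa_alt), c("R", "T"))
  expect_false(eff$synonymous)
  # GGA glycine: third base A->G is synonymous
  eff <- annotateEffect("GGA", 3, "G")
  expect_identical(c(eff$aa_ref, eff$aa_alt), c("G", "G"))
  expect_true(eff$synonymous)
  # substituting the current base is always synonymous with identical codons
  set.seed(10)
  for (i in 1:10) {
    s <- randomSeq(12)
    pos <- sample(1:12, 1)
    eff <- annotateEffect(s, pos, substr(s, pos, pos))
    expect_true(eff$synonymous)
    expect_identical(eff$codon_ref, eff$codon_alt)
  }
  expect_error(annotateEffect("ACGTA", 5, "T"), "partial codon")
  expect_error(annotateEffect("ACGTA", 1, "T", frame = 2), "precedes")
})

test_that("callVariants assembles classification and mutation type per column", {
  groups <- c(d1 = "dura", d2 = "dura", p1 = "pisifera", p2 = "pisifera")
  rows <- c(d1 = "GGAAC", d2 = "GGATC", p1 = "GGTAC", p2 = "GGTAC")
  # col 3: dura A / pisifera T fixed difference; col 4: d2 private T
  aln <- toyAlignment(rows, groups)
  vt <- callVariants(aln)
  expect_identical(vt$column, c(3L, 4L))
  expect_identical(vt$classification, c("diagnostic", "private"))
  expect_identical(vt$carrier, c(NA_character_, "d2"))
  expect_identical(vt$ti_tv, c("transversion", "transversion"))
})
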