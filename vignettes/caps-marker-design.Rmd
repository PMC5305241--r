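---
title: "CAPS marker design and in-silico validation for the oil palm SHELL locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CAPS marker design and in-silico validation for the oil palm SHELL locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsScreen)
```

## The problem and the assay

Oil palm fruit forms — thick-shelled *dura* (Sh/Sh), shell-less *pisifera*
(sh/sh) and the commercial thin-shelled hybrid *tenera* (Sh/sh) — are fixed by
a single codominant locus (*SHELL*, a SEEDSTICK-homologous MADS-box gene), but
are only distinguishable in the field after 4–5 years of growth. A CAPS
(cleaved amplified polymorphic sequence) marker solves this at the seedling
stage: a locus-specific PCR product is digested with a restriction enzyme
whose recognition site is created by one allele and destroyed by the other,
so the gel band pattern reads out the genotype directly.

`capsScreen` models the complete assay: the EgSHP primer pair amplifies a
550 bp product from the *SHELL* locus; an A/T SNP inside the product (the
"diagnostic" SNP) completes a single HindIII site (`AAGCTT`) on the
dura-type allele and removes it on the pisifera-type allele. Digestion
therefore yields two fragments for dura homozygotes, one uncut band for
pisifera homozygotes and all three bands for tenera heterozygotes. At the
protein level, the SNP converts a lysine codon (AAA) to asparagine (AAT) in
the GLLKKAY/GLLKNAY heptapeptide context.

## The pipeline

```{r pipeline, eval = FALSE}
res <- runPipeline(list(seed = 1, out_dir = "caps_run"))
```

runs every stage against a seeded synthetic cohort and writes a manifest:

1. **simulate** — build the two amplicon alleles and a diploid cohort
   (default: 80 dura×pisifera and 60 tenera×tenera progenies).
2. **pcr** — locate primer binding sites (IUPAC-aware, exact 3' terminus) and
   extract the predicted product from every template.
3. **mine-ssrs** — microsatellite survey of the templates.
4. **discover-snps** — variant columns of the labelled panel alignment,
   classified diagnostic / private / uninformative, with codon effects.
5. **design-caps** — differential restriction sites near variants, ranked by
   gel practicality.
6. **genotype** — digest, band-merge, call fruit forms, test segregation.
7. **associate** — single-marker GLM scan when a trait table is supplied.

## The models and their assumptions

### In-silico PCR

Primer matching is IUPAC-compatible (a template `N` matches anything) with a
mandatory exact match at the primer's 3'-terminal base, reflecting that
polymerase extension tolerates internal mismatches far better than terminal
ones. The default mismatch allowance is 0 because the modelled assay is a
single robust product; every forward/reverse site pair inside the 100–2000 bp
window is reported, and downstream stages refuse to guess when a template
yields more than one product.

### Digestion and band patterns

Each recognition site contributes one double-strand cut (`site start − 1 +
cut_top` on the top strand, mirrored for minus-strand sites of
non-palindromic enzymes). Type-IIS enzymes that cut downstream of their site
(MboII, BseMII, EcoP15I in the shipped table) are supported through offsets
beyond the site length; cuts falling off the end of a linear product are
dropped. Substrates are linear PCR products — circular digestion and partial
digestion are deliberately not modelled (the assay's digest is reported
complete at both 2 h and 18 h).

A diploid lane pools the fragments of both haplotypes and merges them by
single linkage within a **band tolerance** (default 15 bp), emulating agarose
resolution; the longest member represents each band. Fruit-form calling then
uses band *counts* against the marker model (cut-hom 2, uncut-hom 1, het 3),
never exact printed sizes: gel estimates of fragment lengths (e.g. "280 and
250 bp" for a 550 bp product) need not sum correctly, so counts are the
robust observable. Size comparisons, where wanted, should use a relative
tolerance of about 10%.

### Diagnostic vs private SNPs

A column is **diagnostic** when the two reference groups (dura and pisifera
by default) are each 100% fixed for different bases — no frequency threshold,
because the marker claim is absolute; sequences from other groups (tenera)
are reported but ignored by the fixation test. A column is **private** when
exactly one sequence in the panel carries the minor allele. Heterozygous
individuals enter the alignment as two haplotype rows, so no IUPAC
heterozygote calling is needed. Transition/transversion labels follow the
standard purine/pyrimidine definition; note that under this definition an
A↔T substitution is a transversion even where assay write-ups sometimes
label it otherwise. Positions are always reported both as alignment columns
and as degapped per-sequence offsets, because published SNP coordinates
rarely state which convention they use.

### Codon effects

The reading frame is part of the marker model, defaulting to frame 1 of the
21-mer codon context around the diagnostic SNP (`GGA CTG CTG AAG AAA GCT
TAT`); the frame of the full amplicon relative to the transcript is not part
of the model. Codons containing ambiguity codes translate to `X` rather than
erroring, since sequenced traces may contain `N`.

### SSR mining

Perfect tandem repeats of period 1–6 are reported at the class-specific
minimum repeat counts 10 / 6 / 4 / 3 / 3 / 3 (mono → hexa), the conventional
EST-SSR thresholds for this assay family. Hits are maximal; a motif that is
itself a repetition of a shorter motif is reported only at the shortest
period (an `ATAT` run is a dinucleotide, never a tetranucleotide), matching
standard SSR-miner behaviour and avoiding double counting. Compound or
interrupted repeats are not merged — the literature rarely defines how they
were counted, so no convention is invented; `N` breaks a run.

### CAPS candidate discovery and ranking

For an aligned gap-free allele pair, every enzyme whose site-position sets
differ between the alleles, with a differing site within a window (default
30 bp) of a differing base, is a candidate. Ranking formalises "a good gel":
all fragments at least 80 bp (visibility) and the fragments unique to one
allele separated from those unique to the other by at least 30 bp
(scorability); ties break by fewer total fragments, then name.

### The synthetic cohort

The generator is the package's stand-in for the sequenced amplicons and
validation cohorts, with their published structure as defaults: a 550 bp
product bracketed by the printed 25/24-nt EgSHP primers, the diagnostic A/T
SNP at position 248 inside the planted single HindIII site, and a private
G→A SNP at position 169 carried by one dura individual (`CD100`). Background
sequence is uniform random from the seed, then scrubbed by local rewrites so
that no spurious HindIII site or primer match survives in either allele or
any template — the single-site, single-product assumptions the assay relies
on are guaranteed, not merely probable. Flanks (default 200 bp per side) are
random because the true genomic context of the product is unknown. The
default places the cut at position 247, giving 247/303 bp fragments; whether
the real dura fragments are gel-separable at 15 bp tolerance cannot be
derived from printed gel estimates, so this separability is a modelling
choice, not a reproduced fact. When a per-base error rate is enabled,
substitutions never touch primer landing sites or planted SNPs (assay
robustness under sequencing error is not the simulated question).

What the generator does *not* emulate: real flanking sequence, indels,
chromatogram noise, partial digestion, band-intensity differences, and
population structure in the cohort. Tests passing on synthetic cohorts
therefore certify the pipeline's logic, not the wet-lab assay's robustness.

Crosses are single-locus Mendelian draws: dura×pisifera progeny are forced
heterozygotes; tenera×tenera progeny segregate 1:2:1. Cohort screening tests
observed class counts with a chi-square goodness of fit (df = expected
classes − 1; for the all-heterozygote expectation the statistic degenerates
and any off-class call is reported as a contamination flag instead).

### Association scan

The marker enters the GLM as a categorical factor (k−1 indicators) — the
fruit-form marker is a three-class codominant factor, and additive dosage
coding would impose an unverified ordering. The trait is regressed on
intercept + structure covariates (a Q matrix, consumed as given) + marker;
the marker is tested by a partial F against the covariates-only model, and
its variance share is the partial R² `(RSS_reduced − RSS_full)/TSS` (whether
published R² values are partial or model-total is usually unstated; partial
is this package's documented choice). Missing and unresolved calls are
excluded pairwise per trait. No multiple-testing correction is applied —
the convention for this assay family is raw thresholds 0.01/0.001 — but
every scan reports its expected false-positive count under the global null.
Kinship-based mixed models are out of scope.

## Numerical choices and degenerate inputs

* Coordinates are 1-based and inclusive on the forward strand everywhere
  user-facing.
* Band tolerance 15 bp and the 80/30 bp ranking limits are agarose-scale
  conventions, all exposed as arguments.
* Ragged alignments, empty FASTA files, unknown cross labels, empty
  reference groups and identical alleles fail fast with named errors;
  an unrecognisable band pattern is the value `"unresolved"`, not an error.
* Monomorphic markers are skipped with a reason, never an exception, so a
  scan always completes; aliased marker columns are dropped with a warning
  and contribute zero incremental R².
* All randomness flows from one top-level seed through named per-stage
  substreams, so adding a stage never perturbs another stage's draws, and a
  run is byte-reproducible from its serialised resolved configuration.

## Verification, problem sizes, and limitations

The test suite checks the site scanner and the SSR miner against independent
brute-force oracles on random sequences, the classifier against exhaustive
enumeration of small panels, fragment-length conservation, involution and
round-trip identities, and end-to-end truth recovery on emitted cohorts. The
calibration experiments use the cohort sizes the assay family reports
(80 DxP + 60 TxT validation samples; n = 100 for association, 1000 null
replicates, 500 power replicates, 200 segregation seeds) — sizes chosen as
representative study scale.

Two honest boundaries are worth stating. First, the package analyses the
*synthetic* stand-in for the deposited amplicon sequences; anyone with the
GenBank accessions can align them and run `callVariants()` directly, and the
coordinate conventions are reported both ways for that purpose. Second, for
a marker generating 12% of phenotypic variance at n = 100, the analytic
power of the partial-F test at α = 0.001 is only ≈0.5 for a three-class
marker (≈0.62 binary) — roughly n ≥ 175 would be needed for 90% power — so
single-study significance claims at that effect size and threshold should be
read with that in mind; the Monte Carlo in the acceptance suite measures
exactly this.
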