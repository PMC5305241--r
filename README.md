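# capsScreen

CAPS marker design and in-silico validation, built around the oil palm
**SHELL** fruit-form assay.

Oil palm fruit forms — thick-shelled *dura* (Sh/Sh), shell-less *pisifera*
(sh/sh) and the commercial hybrid *tenera* (Sh/sh) — are set by one
codominant locus but only visible in the field after 4–5 years. A CAPS
(cleaved amplified polymorphic sequence) marker types seedlings instead: a
550 bp PCR product of the SHELL locus (EgSHP primers) is digested with
HindIII, whose site `AAGCTT` is completed by the dura allele's `A` and
destroyed by the pisifera allele's `T` at the diagnostic SNP. The digest
reads out the genotype as band counts — dura 2, tenera 3, pisifera 1 — and
at the protein level the SNP is a lysine→asparagine change
(GLLK**K**AY → GLLK**N**AY).

The package is for marker developers and breeding programmes: it implements
every computational stage of developing and validating such a marker —

* **SSR mining** (`findSSRs`, `mineSSRs`) with class-specific repeat
  thresholds (mono ≥ 10, di ≥ 6, tri ≥ 4, tetra/penta/hexa ≥ 3);
* **in-silico PCR** (`findBindingSites`, `amplify`) with IUPAC-aware
  matching and a mandatory exact 3' terminus;
* **SNP discovery and classification** (`callVariants`, `classifyColumn`) in
  group-labelled alignments — *diagnostic* (fixed difference between groups)
  vs *private* (single carrier) — with transition/transversion and
  codon-effect annotation (`annotateEffect`);
* **CAPS design** (`scanSites`, `findCapsCandidates`, `rankCandidates`):
  enzymes whose site sets differ between alleles near a variant, ranked by
  gel practicality;
* **digestion and genotyping** (`digestSeq`, `diploidBandPattern`,
  `callFruitForm`, `screenCohort`) with Mendelian segregation chi-square
  tests (DxP all-heterozygote; TxT 1:2:1);
* **association scanning** (`fitSingleMarker`, `scanMarkers`): single-marker
  GLM with structure covariates, partial-F test and partial R²;
* a **seeded synthetic-cohort generator** (`generatorConfig`, `makeAlleles`,
  `emitCohort`, `makePanel`) emulating the assay's amplicon so the whole
  pipeline runs and is testable with no external data.

The statistic at the core of the association stage: for trait *y*, marker
factor *g* and structure covariates *Q*,

    y = Xβ + ε,  X = [1 | Q | g],   F = ((RSS₀ − RSS₁)/Δdf) / (RSS₁/df_e),
    R²_marker = (RSS₀ − RSS₁) / TSS

where RSS₀ is from the covariates-only fit.

## Worked example

```r
library(capsScreen)

cfg   <- generatorConfig(seed = 1)      # 550 bp amplicon, SNPs at 248 / 169
al    <- makeAlleles(cfg)
model <- shellMarkerModel()             # EgSHP + HindIII, tolerance 15 bp

# a heterozygote lane
gt <- genotypeSample(al[["cut"]], al[["uncut"]], model, amplified = TRUE)
gt$pattern
#> BandPattern (3 bands, tolerance 15 bp): 550 / 303 / 247
gt$call
#> [1] "tenera"

# variant discovery on a labelled 12-haplotype panel
vt <- callVariants(makePanel(cfg))
vt[, c("column", "bases", "classification", "carrier", "ti_tv")]
#>   column bases classification carrier        ti_tv
#> 1    169   A/G        private   CD100   transition
#> 2    248   A/T     diagnostic    <NA> transversion

# which enzyme makes the CAPS?
cands <- rankCandidates(findCapsCandidates(al[["cut"]], al[["uncut"]]))
cands[, c("enzyme", "differential", "variant_pos", "site_pos", "retained")]
#>    enzyme differential variant_pos site_pos retained
#> 1 HindIII    destroyed         248      247     TRUE

# the protein-level effect of the diagnostic SNP
annotateEffect("GGACTGCTGAAGAAAGCTTAT", 15, "T")
#>   pos frame codon_start codon_ref codon_alt aa_ref aa_alt synonymous
#> 1  15     1          13       AAA       AAT      K      N      FALSE
```

Reading the output: the heterozygote shows the uncut 550 bp band plus the
two cut fragments (247/303 bp, exact in-silico sizes) — three gel-resolvable
bands, hence the `tenera` call. The panel scan recovers exactly the two
planted SNPs: the private one at 169 attributed to its single dura carrier,
and the group-diagnostic one at 248 whose A→T substitution destroys the
HindIII site and changes K to N. Among the five screened enzymes only
HindIII survives the gel-practicality ranking.

`runPipeline(list(seed = 1, out_dir = "caps_run"))` chains all stages and
writes TSV outputs, a checksummed manifest and the resolved configuration;
re-running from that configuration reproduces every table byte for byte.

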