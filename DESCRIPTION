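Package: capsScreen
Title: CAPS Marker Design and Cohort Screening for the Oil Palm SHELL Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design and in-silico validation of cleaved amplified polymorphic
    sequence (CAPS) markers, built around the oil palm SHELL (Sh) fruit-form
    assay. Covers microsatellite (SSR) motif mining with class-specific repeat
    thresholds, in-silico PCR with IUPAC-aware primer matching, discovery and
    classification of diagnostic versus private SNPs in group-labelled
    alignments with codon-level effect annotation, differential
    restriction-site (CAPS) candidate discovery and ranking, in-silico
    digestion with diploid band-pattern formation and fruit-form genotype
    calling, cohort screening with Mendelian segregation checks, and a
    single-marker GLM association scan with population-structure covariates.
    A seeded synthetic-cohort generator emulates the assay's amplicon
    structure so the whole pipeline runs and is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    seqinr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'iupac.R'
    'seq-utils.R'
    'classes-alignment.R'
    'fasta-io.R'
    'classes-enzyme.R'
    'classes-marker.R'
    'ssr.R'
    'pcr.R'
    'variants.R'
    'caps.R'
    'digest.R'
    'simulate.R'
    'association.R'
    'pipeline.R'
    'capsScreen-package.R'
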