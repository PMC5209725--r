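Package: hcpanel
Title: Coverage QC, Exon-Level CNV Calling and Variant Triage for
    Hereditary Cancer Gene Panels
Version: 0.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Downstream analysis toolkit for targeted hereditary-cancer
    gene-panel diagnostics. Computes per-sample diagnostic coverage
    metrics (C30, uniformity) against padded exonic regions of interest
    and emits Sanger-fallback gap reports; calls exon-level copy-number
    events from multi-sample read-depth matrices via successive
    normalisation with per-sample quality exclusion; applies
    clinically-driven gene-set, region, rarity and read-support filters
    to annotated variants with consensus in-silico pathogenicity
    classification; computes validation statistics with exact binomial
    confidence intervals and replicate concordance; summarises the
    rare-variant landscape as a gene-by-sample matrix; and simulates
    panels, coverage and variant tables with ground truth so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    IRanges,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
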