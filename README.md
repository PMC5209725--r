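# hcpanel

Downstream analysis toolkit for targeted hereditary-cancer gene-panel
diagnostics. It is written for the dry-lab side of a genetic diagnostics
unit: given a panel definition (padded coding exons of cancer-predisposition
genes), per-base depth files and annotated variant tables from a locked
upstream caller, it enforces the diagnostic coverage contract, calls
exon-level copy-number events, filters and classifies variants along
clinically defined gene sets, computes validation statistics with exact
binomial confidence intervals, and summarises the rare-variant landscape
across a cohort. A seeded synthetic-cohort generator makes every component
testable without sequencing data.

## What it computes

* **Coverage QC** — per-sample mean depth; *C30*, the fraction of ROI bases
  covered at >= 30x (the diagnostic-quality criterion); *uniformity*, the
  fraction of bases within +/-20% of the mean; and the Sanger-fallback gap
  report: any analysed ROI with a single base below 30x is listed for
  orthogonal sequencing.
* **Exon-level CNV calling** — from an exon x sample mean-depth matrix,
  successive normalisations (per-sample median library-size correction, then
  a leave-one-out median cross-sample reference) yield copy ratios; samples
  with over-dispersed log2 ratios (unscaled MAD > 0.15) are excluded; states
  are seeded at ratio thresholds 0.65 / 0.25 / 1.35 (het-del / hom-del /
  dup), extended across boundary exons at midpoint thresholds, and merged
  into events with whole-gene and confidence flags.
* **Variant triage** — caller sanity thresholds re-applied as a contract
  (depth >= 10, alt reads >= 2, mean alt base quality >= 15, VAF >= 0.10),
  clinical gene-set and ROI region filters, and the rarity rule (MAF < 1% in
  every recorded population; novel variants kept). Five predictor verdicts
  (PolyPhen2 HDIV/HVAR, SIFT, PROVEAN, MutationTaster) are combined under
  two consensus policies: *landscape* (neutral iff > 3 predictors neutral)
  and *report* (deleterious iff >= 3 damaging). Every removed variant is
  logged with the rule that removed it.
* **Validation statistics** — detection comparison over normalised variant
  keys; sensitivity/specificity with exact Clopper–Pearson intervals
  (lower = B_{a/2}(x, n-x+1), upper = B_{1-a/2}(x+1, n-x)); replicate
  concordance = |common| / |union| with an exact CI.
* **Variant landscape** — the gene x sample matrix of retained rare
  variants, each cell displaying its most damaging class, with per-sample
  burdens, per-gene totals (causal mutations excluded from ordering),
  top-decile gene share and multi-hit tallies.

## Worked example

```r
library(hcpanel)

cfg      <- sim_config(seed = 1)              # 12 genes, 16 samples, 400x
panel    <- simulate_panel(cfg)
profiles <- simulate_coverage(panel, cfg)

summarize_coverage(profiles[[1]])
#> <coverage_summary> sample S01: mean depth 330.4, C30 100.0%,
#>     uniformity 40.4% (23924 bases)

truth <- default_cnv_events(panel, sprintf("S%02d", 1:16))
sp    <- spike_cnv(profiles, truth, cfg)
call_cnvs(build_matrix(sp$profiles, panel))$calls
#>   sample   gene chrom start   end exon_first exon_last n_exons   state
#> 1    S01 GENE01  chr1  9980 28564          1        11      11 het_del
#> 2    S02 GENE02  chr2 11813 15145          2         3       2 het_del
#> 3    S03 GENE03  chr3 12784 17312          2         4       3     dup
#>   mean_ratio whole_gene confidence
#> 1      0.529       TRUE       high
#> 2      0.521      FALSE       high
#> 3      1.534      FALSE       high

clopper_pearson(123, 136)
#> 123/136 = 90.4% (84.2-94.8%), 95% CI, Clopper-Pearson exact
```

The three spiked events (a whole-gene heterozygous deletion, a two-exon
heterozygous deletion, a three-exon duplication) are recovered exactly, and
the exact binomial interval for 123 detections out of 136 known variants
prints the sensitivity figure a validation report would quote.

A command-line wrapper with subcommands `simulate`, `qc`, `gaps`, `cnv`,
`filter`, `classify`, `landscape` and `stats` is installed at
`inst/cli/hcpanel`; every run writes a manifest recording the effective
thresholds, input digests and seed.

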