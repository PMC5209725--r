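---
title: "Methods behind hcpanel: coverage QC, exon-level CNV calling and variant triage for hereditary-cancer panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind hcpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcpanel)
```

## Scope

`hcpanel` implements the downstream computational core of a targeted
hereditary-cancer gene-panel diagnostic workflow: everything after an
external aligner and variant caller have produced per-base depths and
annotated variant tables. The package does not align reads, call SNVs or
run annotation engines; it enforces the diagnostic contract on their
outputs. All analyses are exercisable on synthetic cohorts produced by
the package's own generator, so no sequencing data are required to test
any component.

## Regions of interest

Diagnostic panels target all coding exons plus the intronic bases where
splice-affecting variants concentrate. `pad_exons()` widens each exon by
35 bases on the splice-acceptor side and 20 on the donor side
(defaults), interpreted in transcription orientation: a minus-strand
exon receives its 35-base pad on the genomic right. Published panel
descriptions rarely state whether such padding is strand-aware, so a
`strand_aware = FALSE` switch provides the genomic left/right reading;
we default to the transcription-orientation convention because the
asymmetry of the pads mirrors the asymmetry of splice signals (the
acceptor's branch point and polypyrimidine tract reach deeper into the
intron than the donor motif). Coordinates are 0-based half-open
everywhere inside the package (BED convention); 1-based coordinates
appear only at variant-file ingestion.

Overlapping isoform exons are unioned per gene by `merge_rois()` before
coverage or copy-number work, because capture and depth are properties
of the locus, not of a transcript. Exon ordinals are renumbered along
the transcription direction after merging.

## Coverage quality control

Three per-sample metrics are computed over unique ROI bases:

* **mean depth** — the plain mean of per-base depths;
* **C30** — the fraction of bases with depth at or above the diagnostic
  minimum of 30x. The 30x floor is the long-standing threshold for
  confident germline heterozygote detection on capture panels;
* **uniformity** — the fraction of bases whose depth lies within
  plus/minus 20% of the sample mean, both endpoints inclusive. The mean
  is used unrounded; inclusivity at the endpoints makes the statistic
  reproducible across floating-point paths.

The Sanger-fallback rule is deliberately strict: any analysed ROI with a
*single* base under 30x is reported by `find_sanger_regions()` for
orthogonal sequencing. Gap reporting is restricted to the clinically
selected gene set, because the fallback is an action taken per reported
gene; global metrics, by contrast, always describe the unique-base union
of the panel.

## Exon-level copy-number calling

`call_cnvs()` detects constitutional deletions and duplications from an
exon-by-sample matrix of mean depths via successive normalisations:

1. each sample's column is divided by its median exon depth
   (library-size correction — calls must be invariant to sequencing
   yield);
2. each exon's row is divided by a cross-sample reference. The default
   reference is the **leave-one-out median**: for sample $s$ the
   reference of exon $e$ is the median of the other samples'
   library-normalised depths. With batches of 12-16 samples, a real
   whole-gene deletion would contaminate a reference that included the
   tested sample; the leave-one-out median keeps the reference clean
   while remaining robust to one aberrant other sample. An
   `all_median` mode is provided for comparison and agrees with the
   default on clean batches (this is property-tested);
3. ratios are log2-transformed with a floor at $2^{-8}$ so zero-depth
   exons remain finite.

Exons with zero reference depth in every sample are masked (capture
dropout, not biology). Samples whose unmasked log2 ratios have an
unscaled median absolute deviation above 0.15 are excluded from calling
entirely — an over-dispersed sample cannot support exon-level inference,
and excluding it mirrors diagnostic practice of failing a sample rather
than reporting doubtful calls. The MAD is used unscaled (no 1.4826
consistency factor): the cutoff is a direct statement about ratio
spread, not an estimate of a Gaussian sigma.

States are assigned per exon from the copy ratio with thresholds placed
between the expected ratios of diploid (1), one-copy (0.5), zero-copy
(0) and three-copy (1.5) loci, with guard bands: at or below 0.65 is a
heterozygous deletion, at or below 0.25 homozygous, at or above 1.35 a
duplication. Bounds are inclusive on the event side. Calling is then
**seed-and-extend**: hard thresholds seed an event, and a neutral exon
adjacent to a seeded run joins it when its ratio passes the midpoint
extension threshold for that state (0.75, 0.375 and 1.25 respectively).
With multiplicative exon noise around 5%, a boundary exon of a true
duplication sits ~2 standard deviations from the 1.35 hard threshold,
so hard thresholds alone occasionally split multi-exon events; the
extension pass repairs exactly this failure mode while an isolated
neutral exon (ratio near 1) is more than 4 standard deviations from any
extension threshold, so extension does not create events.

An isolated exon with zero raw depth in one sample is reported as
*uncallable* rather than a homozygous deletion — a single-exon capture
dropout is the more likely explanation — unless at least two
consecutive exons of the gene are zero, which restores the homozygous
interpretation. Runs of same-state exons are merged by `merge_calls()`;
an event spanning every exon of its gene is flagged whole-gene, and
single-exon events carry low confidence (they rest on one measurement
and, in practice, warrant orthogonal MLPA confirmation).

## Variant filtering and classification

Variants arrive as annotated tables (TSV, or VCF through `vcfR`) and
are normalised on ingestion: shared allele bases trimmed and indels
left-aligned against a reference sequence when one is supplied, so the
same physical change always maps to one `(sample, chrom, pos, ref, alt)`
key. Four pure filters follow, in any order (they commute, and every
removed variant is logged with the rule that removed it):

* **sanity** — the locked parameters of the upstream caller re-applied
  as a contract: depth >= 10, alt reads >= 2, mean alt base quality
  >= 15, VAF >= 0.10, all inclusive on the keep side; a missing metric
  does not apply its test;
* **gene set** — only genes with clinical utility for the patient's
  condition are analysed; gene sets are clinician-defined plain-text
  lists;
* **region** — the variant's position must fall inside a padded ROI
  (start inclusive, end exclusive);
* **rarity** — every recorded population frequency must be strictly
  below 1%. Variants absent from all frequency databases are kept:
  absence of a record cannot make a variant common, and novel variants
  are precisely the ones a rare-disease workflow must not discard.

Five in-silico predictors (PolyPhen2 HDIV and HVAR, SIFT, PROVEAN,
MutationTaster) are combined by `consensus_prediction()` under two
deliberately distinct policies used at different points of the
workflow: the *landscape* policy calls a variant neutral only when more
than 3 predictors agree it is neutral, while the *report* policy calls
it deleterious when 3 or more predictors call it damaging. Missing
verdicts count toward neither threshold. The policies disagree on the
(3 neutral, 2 damaging) configuration by construction; both are
exposed, and the package does not assert that either is the "true"
rule. Within a gene-sample cell, `most_damaging()` ranks
cnv > nonsense > frameshift > splicing > missense (possibly damaging) >
missense (neutral) > synonymous > other, ties broken by position; the
placement of CNV at the top is a package convention.

## Validation statistics

Detection comparisons are set-theoretic over normalised variant keys.
Sensitivity and specificity carry exact Clopper–Pearson intervals
computed from Beta quantiles: lower $= B_{\alpha/2}(x,\,n-x+1)$, upper
$= B_{1-\alpha/2}(x+1,\,n-x)$, with the closed forms at $x=0$ and
$x=n$. The implementation is cross-checked in the test suite against
`stats::binom.test` to $10^{-12}$. Replicate concordance (within-run
repeatability, between-run reproducibility) is the number of common
variants divided by the total identified; *total* is read as the union
of the two runs' sets — the only reading that keeps the statistic at or
below 1 for asymmetric runs.

## Rare-variant landscape

`build_landscape()` arranges retained variants as a gene-by-sample
matrix: genes ordered by descending non-causal variant totals
(disease-causing mutations are flagged but excluded from gene ordering,
so the landscape describes the variation that *coexists* with the
causal mutation), samples grouped by clinical condition then ordered by
burden; ties break alphabetically so exports are deterministic.
Summary statistics include the per-sample burden distribution, the
share of non-causal variation carried by the top decile of genes
(decile count = ceiling of 10% of genes with at least one non-causal
variant — the ceiling guarantees a non-empty decile on small panels),
and multi-hit tallies (gene-sample pairs carrying two or more
variants).

## The synthetic cohort generator

`sim_config()` defaults define the study conditions for every test in
the package:

* per-sample mean exonic depth 400x, negative-binomial per-base depth
  with dispersion `size = 10`, log-normal library-size factors
  (sd 0.1) — the working regime of a mid-size capture panel on a
  benchtop sequencer;
* a quadratic GC penalty centred at GC 0.45 and a linear depth ramp in
  the intronic flanks falling to 30% of exonic depth at the outermost
  padded base, mimicking the empirical falloff of capture efficiency
  across intron-exon boundaries;
* per-(exon, sample) multiplicative log-normal noise with sd 0.05.
  This is read as noise that does *not* cancel between a sample and
  its reference — the stringent interpretation, since a purely
  per-exon effect shared by all samples would be removed exactly by
  the cross-sample normalisation and would test nothing;
* spiked copy-number events scale expected depth by 0.5, 0.02 or 1.5
  before resampling;
* per-sample non-causal variant burdens follow a Poisson truncated to
  [1, 9] whose rate is solved (by `uniroot`) so the *truncated* mean
  equals 5 — the reported cohort statistic is the observed average
  burden, so the generator is calibrated on that scale rather than on
  the raw rate (a plain Poisson(5) truncated to [1, 9] has mean only
  ~4.85);
* exactly one causal variant per sample, placed in a gene of the
  sample's clinical condition set; non-causal variants choose genes
  with probability proportional to captured bases (mutation
  opportunity scales with target size);
* predictor verdicts are correlated with consequence class, MAFs come
  from a novel/log-uniform mixture, and small configured fractions of
  variants are placed off-target or given failing read support so
  every filter branch is exercised by the default fixture.

What the generator does *not* emulate: homopolymer and mapping
artifacts, pseudogene interference, batch-correlated capture drift, or
any linkage between variants. Tests passing on synthetic cohorts
therefore demonstrate the correctness and calibration of the
*algorithms* under the stated statistical assumptions, not the
performance of the full strategy on real libraries — which is exactly
why the original workflow retains Sanger fallback and MLPA
confirmation, and why this package treats those rules as first-class
outputs rather than optional extras.

Problem sizes used throughout the test and acceptance suites — 12-gene
panels, 16-sample batches for copy-number recovery (20 replicate
fixtures), 60-sample cohorts for landscape statistics — were chosen as
the smallest sizes at which the cohort-level statistics stabilise;
per-seed sampling error at these sizes is quoted alongside each check
(for example, a 60-sample burden mean has standard error ~0.26, so the
burden-recovery check scores the mean pooled across the 20 replicate
cohorts).

## Numerical and degenerate-input conventions

Zero-length intervals are rejected at parse time. A depth file missing
a panel base contributes depth 0. A panel with zero ROI bases is an
error for coverage summaries. Copy-number calling refuses cohorts of
fewer than two samples (no reference can be formed) and errors on a
sample whose median exon depth is zero. `clopper_pearson()` requires at
least one trial; concordance of two empty runs is undefined and raised
as an error rather than returned as NaN. Exported tables are written
with fixed column order and deterministic row order so byte-identical
re-export is guaranteed for identical inputs; the run manifest is the
single output that differs between reruns (it records wall-clock
time).

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
panel <- simulate_panel(cfg)
profiles <- simulate_coverage(panel, cfg)
summarize_coverage(profiles[[1]])

truth <- default_cnv_events(panel, sprintf("S%02d", 1:16))
sp <- spike_cnv(profiles, truth, cfg)
call_cnvs(build_matrix(sp$profiles, panel))$calls

vt <- simulate_variant_tables(panel, cfg)
v <- rare_filter(filter_by_region(sanity_filter(vt$variants), panel))
landscape_stats(build_landscape(v, vt$conditions))
```

## Known limitations

The copy-number caller is exon-resolution only: breakpoints inside
exons, balanced events and events shorter than one exon are invisible,
and single-exon calls are intrinsically low-confidence. The consensus
classifier ingests externally computed predictor verdicts and cannot
improve on their quality. The landscape statistics describe retained
variants only; any bias introduced upstream (capture design, caller
blind spots) propagates into them. None of the package's outputs
constitute clinical classification; they order and annotate evidence
for a human reviewer.
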