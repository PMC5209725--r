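# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdirs.

tiny_panel <- function() {
  hcpanel:::new_panel(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(100L, 300L, 600L, 50L),
    end   = c(200L, 400L, 700L, 150L),
    gene  = c("BRCA1", "BRCA1", "BRCA1", "MLH1"),
    transcript = "", exon = c(1L, 2L, 3L, 1L),
    strand = c("+", "+", "+", "-"),
    stringsAsFactors = FALSE), name = "tiny")
}

# constant-depth profile over a panel
flat_profile <- function(panel, depth, sample = "T1") {
  n <- sum(panel$end - panel$start)
  hcpanel:::new_depth_profile(sample, rep(depth, n), panel)
}

# profile from an explicit per-base vector
vec_profile <- function(panel, depths, sample = "T1") {
  hcpanel:::new_depth_profile(sample, depths, panel)
}

# one-row variant builder with sane defaults
mk_var <- function(sample = "S1", gene = "BRCA1", chrom = "chr1",
                   pos = 150L, ref = "A", alt = "T",
                   consequence = "missense", causal = FALSE,
                   maf_1kg = NA_real_, maf_exac = NA_real_,
                   preds = rep("neutral", 5),
                   depth = 200, alt_reads = 90, vaf = alt_reads / depth,
                   alt_qual = 35, alt_fwd = 45, alt_rev = 45,
                   alt_mismatches = 1, read_pos_sd = 60) {
  df <- data.frame(sample = sample, gene = gene, chrom = chrom, pos = pos,
                   ref = ref, alt = alt, consequence = consequence,
                   zygosity = "het", causal = causal,
                   maf_1kg = maf_1kg, maf_exac = maf_exac,
                   pred_polyphen2_hdiv = preds[1],
                   pred_polyphen2_hvar = preds[2],
                   pred_sift = preds[3], pred_provean = preds[4],
                   pred_mutationtaster = preds[5],
                   depth = depth, alt_reads = alt_reads, vaf = vaf,
                   alt_qual = alt_qual, alt_fwd = alt_fwd,
                   alt_rev = alt_rev, alt_mismatches = alt_mismatches,
                   read_pos_sd = read_pos_sd, stringsAsFactors = FALSE)
  hcpanel:::as_variants(df)
}

mk_vars <- function(...) {
  pieces <- lapply(list(...), as.data.frame)
  hcpanel:::as_variants(do.call(rbind, pieces))
}

# brute-force per-base coverage oracle (independent of the package path)
oracle_coverage <- function(depths, min_depth = 30, window = 0.2) {
  m <- 0; for (d in depths) m <- m + d
  m <- m / length(depths)
  n30 <- 0; nu <- 0
  for (d in depths) {
    if (d >= min_depth) n30 <- n30 + 1
    if (d >= (1 - window) * m && d <= (1 + window) * m) nu <- nu + 1
  }
  list(mean = m, c30 = n30 / length(depths), uniformity = nu / length(depths))
}
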