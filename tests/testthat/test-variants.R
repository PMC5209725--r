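test_that("variant TSV round-trips with missing annotations kept missing", {
  dir <- withr::local_tempdir()
  v <- mk_vars(mk_var(pos = 150L),
               mk_var(pos = 320L, consequence = "nonsense",
                      preds = c("damaging", "damaging", NA, "damaging",
                                "neutral")))
  path <- file.path(dir, "v.tsv")
  write_variants(v, path)
  v2 <- read_variant_table(path)
  expect_equal(nrow(v2), 2)
  expect_equal(v2$pos, v$pos)
  expect_true(is.na(v2$pred_sift[2]))
  expect_equal(v2$pred_polyphen2_hdiv[2], "damaging")
})

test_that("indel normalisation matches an exhaustive-shift oracle", {
  # toy 30 bp reference with a homopolymer and a dinucleotide repeat
  seqc <- "GGTACACACACATTTTTTGCAGTCAGTCAG"
  refseq <- c(chr1 = seqc)
  apply_change <- function(pos, ref, alt) {
    stopifnot(substr(seqc, pos, pos + nchar(ref) - 1) == ref)
    paste0(substr(seqc, 1, pos - 1), alt,
           substr(seqc, pos + nchar(ref), nchar(seqc)))
  }
  # oracle: slide an anchored representation of fixed allele lengths over
  # every position of the toy reference; the leftmost one that reproduces
  # the edited sequence is the canonical form
  oracle_leftmost <- function(target, dr, da) {
    for (p in seq_len(nchar(seqc) - dr + 1)) {
      r <- substr(seqc, p, p + dr - 1)
      a <- substr(target, p, p + da - 1)
      if (identical(r, a)) next
      ok <- tryCatch(identical(apply_change(p, r, a), target),
                     error = function(e) FALSE)
      if (ok) return(list(pos = p, ref = r, alt = a))
    }
    NULL
  }
  cases <- list(
    list(pos = 10L, ref = "ACA", alt = "A"),  # CA-repeat deletion
    list(pos = 4L,  ref = "ACA", alt = "A"),  # same event, other frame
    list(pos = 16L, ref = "TT",  alt = "T"),  # homopolymer deletion
    list(pos = 17L, ref = "T", alt = "TT"))   # homopolymer insertion
  for (cs in cases) {
    got <- normalize_variant(cs$pos, cs$ref, cs$alt, chrom = "chr1",
                             refseq = refseq)
    target <- apply_change(cs$pos, cs$ref, cs$alt)
    want <- oracle_leftmost(target, nchar(cs$ref), nchar(cs$alt))
    expect_equal(got[c("pos", "ref", "alt")],
                 list(pos = want$pos, ref = want$ref, alt = want$alt),
                 info = paste(unlist(cs), collapse = "/"))
    # the normalised form still describes the same edit
    expect_identical(apply_change(got$pos, got$ref, got$alt), target)
  }
  # two representations of one deletion share a key after normalisation
  norm_key <- function(pos, ref, alt) {
    n <- normalize_variant(pos, ref, alt, chrom = "chr1", refseq = refseq)
    variant_key(data.frame(sample = "S", chrom = "chr1", pos = n$pos,
                           ref = n$ref, alt = n$alt))
  }
  expect_identical(norm_key(10L, "ACA", "A"), norm_key(4L, "ACA", "A"))
  # different alt alleles at one site keep distinct keys
  expect_false(identical(norm_key(5L, "C", "G"), norm_key(5L, "C", "T")))
})

test_that("sanity filter enforces the locked caller thresholds", {
  keep <- mk_var(depth = 100, alt_reads = 40, alt_qual = 30, vaf = 0.4)
  low_alt <- mk_var(pos = 151L, alt_reads = 1, vaf = 0.005)
  at_vaf <- mk_var(pos = 152L, depth = 100, alt_reads = 10, vaf = 0.10)
  low_depth <- mk_var(pos = 153L, depth = 9, alt_reads = 5, vaf = 0.55)
  out <- sanity_filter(mk_vars(keep, low_alt, at_vaf, low_depth))
  expect_equal(out$pos, c(150L, 152L))  # vaf 0.10 exactly is kept
  audit <- removed_variants(out)
  expect_equal(nrow(audit), 2)
  expect_true(all(audit$removed_by == "sanity"))
  # an absent metric does not apply its test
  na_metric <- mk_var(pos = 154L, depth = NA_real_, alt_reads = NA_real_,
                      vaf = NA_real_, alt_qual = NA_real_,
                      alt_fwd = NA_real_, alt_rev = NA_real_)
  expect_equal(nrow(sanity_filter(na_metric)), 1)
})

test_that("gene-set and region filters keep exactly the in-scope variants", {
  p <- merge_rois(tiny_panel())  # BRCA1 ROIs incl [100,200); MLH1 [50,150)
  inside <- mk_var(pos = 101L)           # 0-based 100 = ROI start: kept
  at_end <- mk_var(pos = 200L)           # 0-based 199: last base, kept
  past_end <- mk_var(pos = 201L)         # 0-based 200 = end: excluded
  deep <- mk_var(pos = 260L)             # 60 bp into the intron
  other_gene <- mk_var(gene = "MLH1", chrom = "chr2", pos = 60L)
  v <- mk_vars(inside, at_end, past_end, deep, other_gene)
  vr <- filter_by_region(v, p)
  expect_equal(vr$pos, c(101L, 200L, 60L))
  vg <- filter_by_geneset(v, geneset("B", "BRCA1"))
  expect_equal(nrow(vg), 4)
  expect_equal(removed_variants(vg)$gene, "MLH1")
  expect_equal(nrow(filter_by_geneset(v, geneset("ALL",
                                                 c("BRCA1", "MLH1")))), 5)
  expect_equal(nrow(filter_by_geneset(v[0, ], geneset("B", "BRCA1"))), 0)
})

test_that("rare filter is strict-below across all populations, novel kept", {
  rare <- mk_var(pos = 150L, maf_1kg = 0.005, maf_exac = 0.009)
  common_one_pop <- mk_var(pos = 151L, maf_1kg = 0.005, maf_exac = 0.02)
  novel <- mk_var(pos = 152L)
  at_cutoff <- mk_var(pos = 153L, maf_1kg = 0.01)
  out <- rare_filter(mk_vars(rare, common_one_pop, novel, at_cutoff))
  expect_equal(out$pos, c(150L, 152L))
  expect_setequal(removed_variants(out)$pos, c(151L, 153L))
})

test_that("filters commute and compose with a complete audit trail", {
  p <- merge_rois(tiny_panel())
  set.seed(21)
  rows <- lapply(1:40, function(i) mk_var(
    gene = sample(c("BRCA1", "MLH1", "OFFPANEL"), 1),
    chrom = sample(c("chr1", "chr2"), 1),
    pos = sample(40:800, 1),
    maf_1kg = if (runif(1) < 0.5) NA_real_ else runif(1, 0, 0.03),
    depth = sample(c(5, 200), 1, prob = c(0.2, 0.8)),
    alt_reads = 2, vaf = sample(c(0.05, 0.5), 1), alt_qual = 30))
  v <- do.call(mk_vars, rows)
  gs <- geneset("B", c("BRCA1", "MLH1"))
  a <- rare_filter(filter_by_region(filter_by_geneset(v, gs), p))
  b <- filter_by_geneset(filter_by_region(rare_filter(v), p), gs)
  expect_equal(variant_key(a), variant_key(b))
  expect_equal(nrow(a) + nrow(removed_variants(a)), nrow(v))
})

test_that("consensus policies match the stated rules on key cases", {
  five_neutral <- mk_var(preds = rep("neutral", 5))
  expect_equal(consensus_prediction(five_neutral, "landscape")$label,
               "neutral")
  expect_equal(consensus_prediction(five_neutral, "report")$label,
               "not_deleterious")
  four_one <- mk_var(preds = c(rep("neutral", 4), "damaging"))
  expect_equal(consensus_prediction(four_one, "landscape")$label, "neutral")
  # the two policies disagree by design on 3 neutral / 2 damaging
  three_two <- mk_var(preds = c(rep("neutral", 3), rep("damaging", 2)))
  expect_equal(consensus_prediction(three_two, "landscape")$label,
               "possibly_damaging")
  expect_equal(consensus_prediction(three_two, "report")$label,
               "not_deleterious")
  three_dmg <- mk_var(preds = c(rep("damaging", 3), rep("neutral", 2)))
  expect_equal(consensus_prediction(three_dmg, "report")$label,
               "deleterious")
  # missing counts toward neither threshold
  miss <- mk_var(preds = c("neutral", "neutral", "neutral", "neutral", NA))
  expect_equal(consensus_prediction(miss, "landscape")$label, "neutral")
  expect_equal(consensus_prediction(miss, "landscape")$n_missing, 1L)
})

test_that("most_damaging follows the severity order, ties by position", {
  g <- mk_vars(mk_var(pos = 150L, consequence = "synonymous"),
               mk_var(pos = 151L, consequence = "nonsense"))
  expect_equal(most_damaging(g)$consequence, "nonsense")
  g2 <- mk_vars(mk_var(pos = 150L, consequence = "splicing"),
                mk_var(pos = 151L, consequence = "frameshift"))
  expect_equal(most_damaging(g2)$consequence, "frameshift")
  # possibly-damaging missense beats neutral missense
  g3 <- mk_vars(mk_var(pos = 150L, preds = rep("neutral", 5)),
                mk_var(pos = 151L, preds = rep("damaging", 5)))
  expect_equal(most_damaging(g3)$pos, 151L)
  # order invariance
  expect_equal(most_damaging(g3[2:1, ])$pos, 151L)
  # tie broken by smaller position
  g4 <- mk_vars(mk_var(pos = 160L, consequence = "nonsense"),
                mk_var(pos = 150L, consequence = "nonsense"))
  expect_equal(most_damaging(g4)$pos, 150L)
  expect_error(most_damaging(g4[0, ]), "empty")
})

test_that("quality flags fire at their documented thresholds", {
  clean <- mk_var(vaf = 0.48, alt_fwd = 45, alt_rev = 45, alt_qual = 35)
  expect_equal(quality_flags(clean), "")
  expect_equal(quality_flags(mk_var(vaf = 0.12, alt_reads = 24)), "low_vaf")
  biased <- mk_var(alt_reads = 12, alt_fwd = 12, alt_rev = 0, vaf = 0.3)
  expect_match(quality_flags(biased), "strand_bias")
  few <- mk_var(alt_reads = 3, alt_fwd = 3, alt_rev = 0, vaf = 0.3)
  expect_false(grepl("strand_bias", quality_flags(few)))
  expect_match(quality_flags(mk_var(alt_qual = 18, vaf = 0.4)),
               "low_base_quality")
  expect_match(quality_flags(mk_var(alt_mismatches = 4, vaf = 0.4)),
               "mismatch_rich")
  expect_match(quality_flags(mk_var(read_pos_sd = 10, vaf = 0.4)),
               "positional_clustering")
})
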