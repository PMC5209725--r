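cohort <- function(seed = 1, n_samples = 16, ...) {
  cfg <- sim_config(seed = seed, n_samples = n_samples, ...)
  panel <- simulate_panel(cfg)
  list(cfg = cfg, panel = panel,
       profiles = simulate_coverage(panel, cfg))
}

test_that("build_matrix computes per-exon means and needs >= 2 samples", {
  p <- tiny_panel()
  prof1 <- flat_profile(p, 100, "A")
  expect_error(build_matrix(list(prof1), p), "at least 2")
  mat <- build_matrix(list(prof1, flat_profile(p, 100, "B")), p)
  expect_true(all(mat$depth == 100))
  # hand-computed exon mean
  depths <- rep(0, sum(p$end - p$start))
  depths[panel_base_map(p)$roi == 1] <- rep(c(10, 20, 30), length.out = 100)
  m2 <- build_matrix(list(vec_profile(p, depths, "A"),
                          flat_profile(p, 50, "B")), p)
  expect_equal(unname(m2$depth[1, "A"]),
               mean(rep(c(10, 20, 30), length.out = 100)))
  # an all-zero column is allowed (it will fail QC later)
  expect_error(build_matrix(list(flat_profile(p, 0, "A"),
                                 flat_profile(p, 50, "B")), p), NA)
})

test_that("identical samples normalise to ratio 1 everywhere", {
  p <- tiny_panel()
  profs <- lapply(sprintf("S%d", 1:4), function(s) flat_profile(p, 200, s))
  r <- cnv_normalize(build_matrix(profs, p))
  expect_true(all(abs(r$ratio - 1) < 1e-12))
  expect_true(all(abs(r$log2_ratio) < 1e-12))
})

test_that("library-size scaling of one sample changes no ratios or calls", {
  co <- cohort(seed = 3)
  mat <- build_matrix(co$profiles, co$panel)
  base <- call_cnvs(mat)
  for (c_ in c(0.5, 2)) {
    mat2 <- mat
    mat2$depth[, 5] <- mat2$depth[, 5] * c_
    scaled <- call_cnvs(mat2)
    expect_equal(as.data.frame(scaled$calls), as.data.frame(base$calls))
  }
})

test_that("spiked half-depth exons come out at ratio ~0.5, rest at ~1", {
  co <- cohort(seed = 4, lib_sd = 0, gc_bias_strength = 0,
               exon_effect_sd = 0, depth_dispersion = Inf)
  ev <- data.frame(sample = "S01", gene = "GENE01", exon_first = 1L,
                   exon_last = sum(co$panel$gene == "GENE01"),
                   state = "het_del", stringsAsFactors = FALSE)
  sp <- spike_cnv(co$profiles, ev, co$cfg)
  r <- cnv_normalize(build_matrix(sp$profiles, co$panel))
  in_gene <- co$panel$gene == "GENE01"
  expect_true(all(abs(r$ratio[in_gene, "S01"] - 0.5) < 0.05))
  expect_true(all(abs(r$ratio[!in_gene, "S01"] - 1) < 0.05))
  expect_true(all(abs(r$ratio[, "S05"] - 1) < 0.05))
})

test_that("sample QC excludes over-dispersed samples", {
  co <- cohort(seed = 6)
  mat <- build_matrix(co$profiles, co$panel)
  r <- cnv_normalize(mat)
  qc <- qc_samples(r)
  expect_true(all(qc$passed))
  expect_true(all(qc$dispersion < 0.15))
  # inject noise: log2 ratios ~ N(0, 0.5) has raw MAD ~0.34 > 0.15
  set.seed(1)
  r$log2_ratio[, 2] <- rnorm(nrow(r$log2_ratio), 0, 0.5)
  qc2 <- qc_samples(r)
  expect_false(qc2$passed[2])
  # an excluded sample produces no calls
  r$ratio[, 2] <- 0.5
  calls <- merge_calls(call_exons(r, qc2), r)
  expect_false("S02" %in% calls$sample)
})

test_that("state thresholds apply with inclusive event-side bounds", {
  p <- tiny_panel()
  profs <- lapply(sprintf("S%d", 1:8), function(s) flat_profile(p, 100, s))
  r <- cnv_normalize(build_matrix(profs, p))
  qc <- qc_samples(r)
  probe <- function(x) {
    r$ratio[2, 1] <- x
    unname(call_exons(r, qc)[2, 1])
  }
  expect_equal(probe(1.0), "neutral")
  expect_equal(probe(0.65), "het_del")
  expect_equal(probe(0.66), "neutral")
  expect_equal(probe(0.25), "hom_del")
  expect_equal(probe(0.5), "het_del")
  expect_equal(probe(1.35), "dup")
  expect_equal(probe(1.34), "neutral")
})

test_that("an isolated zero-depth exon is uncallable, a run is hom_del", {
  p <- tiny_panel()  # BRCA1 has 3 exons
  profs <- lapply(sprintf("S%d", 1:8), function(s) flat_profile(p, 100, s))
  mat <- build_matrix(profs, p)
  mat$depth[2, 1] <- 0          # single exon dropout
  r <- cnv_normalize(mat)
  st <- call_exons(r, qc_samples(r, max_mad = 10))
  expect_equal(unname(st[2, 1]), "uncallable")
  mat$depth[1:2, 1] <- 0        # two consecutive zero exons
  r2 <- cnv_normalize(mat)
  st2 <- call_exons(r2, qc_samples(r2, max_mad = 10))
  expect_equal(unname(st2[1:2, 1]), c("hom_del", "hom_del"))
})

test_that("merge_calls merges runs, flags whole-gene and low confidence", {
  p <- tiny_panel()
  profs <- lapply(sprintf("S%d", 1:8), function(s) flat_profile(p, 100, s))
  r <- cnv_normalize(build_matrix(profs, p))
  qc <- qc_samples(r)
  # two adjacent het_del exons in BRCA1
  r$ratio[1:2, 1] <- 0.5
  calls <- merge_calls(call_exons(r, qc), r)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$n_exons, 2L)
  expect_false(calls$whole_gene)
  expect_equal(calls$confidence, "high")
  # whole gene
  r$ratio[1:3, 1] <- 0.5
  calls2 <- merge_calls(call_exons(r, qc), r)
  expect_true(calls2$whole_gene)
  # single exon flanked by neutral -> low confidence
  r$ratio[1:3, 1] <- 1
  r$ratio[2, 1] <- 0.5
  calls3 <- merge_calls(call_exons(r, qc), r)
  expect_equal(calls3$n_exons, 1L)
  expect_equal(calls3$confidence, "low")
})

test_that("permuting samples permutes calls identically", {
  co <- cohort(seed = 8)
  ev <- default_cnv_events(co$panel, sprintf("S%02d", 1:16))
  sp <- spike_cnv(co$profiles, ev, co$cfg)
  calls_a <- call_cnvs(build_matrix(sp$profiles, co$panel))$calls
  perm <- rev(seq_along(sp$profiles))
  calls_b <- call_cnvs(build_matrix(sp$profiles[perm], co$panel))$calls
  key <- function(x) paste(x$sample, x$gene, x$exon_first, x$exon_last,
                           x$state)
  expect_setequal(key(calls_a), key(calls_b))
})

test_that("loo_median and all_median references agree on clean batches", {
  co <- cohort(seed = 9)
  ev <- default_cnv_events(co$panel, sprintf("S%02d", 1:16))
  sp <- spike_cnv(co$profiles, ev, co$cfg)
  mat <- build_matrix(sp$profiles, co$panel)
  key <- function(x) paste(x$sample, x$gene, x$exon_first, x$exon_last,
                           x$state)
  expect_setequal(key(call_cnvs(mat, reference = "loo_median")$calls),
                  key(call_cnvs(mat, reference = "all_median")$calls))
})
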