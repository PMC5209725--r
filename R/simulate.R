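# Synthetic panel, coverage and variant generator. Emulates the
# statistical structure the downstream methods assume -- negative-binomial
# per-base depth with GC bias and intron-boundary falloff, spiked
# copy-number events, and per-sample rare-variant burdens around 5 --
# and records ground truth so recovery can be scored.

#' Simulation configuration
#'
#' Defaults target the working regime of a diagnostic capture panel:
#' per-sample mean depth 400x, negative-binomial per-base depth
#' (dispersion \code{size = 10}), mild GC bias (quadratic penalty around
#' GC 0.45), flank depth falling to 30\% of exonic depth at the outermost
#' padded base, per-(exon, sample) multiplicative log-normal noise with
#' sd 0.05, and per-sample variant burdens ~ Poisson(5) truncated to
#' [1, 9].
#'
#' @param seed integer; fixes all randomness end-to-end.
#' @param n_genes,n_samples panel and cohort size.
#' @param exons_per_gene integer range (min, max) of exons per gene.
#' @param exon_length_range integer range of unpadded exon lengths.
#' @param mean_depth target per-sample mean exonic depth.
#' @param depth_dispersion negative-binomial size (Inf = Poisson).
#' @param lib_sd sd of per-sample log-normal library-size factor.
#' @param gc_bias_strength coefficient of the quadratic depth penalty in
#'   (GC - 0.45).
#' @param boundary_falloff fraction of exonic depth at the outer edge of
#'   the intronic flanks.
#' @param exon_effect_sd sd of per-(exon, sample) log-normal depth noise.
#' @param pad5,pad3 intronic padding (acceptor/donor side).
#' @param variant_burden mean per-sample non-causal variant count.
#' @param burden_range truncation bounds for the burden.
#' @param maf_novel_frac fraction of variants absent from all frequency
#'   databases; the rest draw MAFs log-uniform on [1e-5, 0.05].
#' @param frac_offtarget fraction of variants placed outside any ROI.
#' @param frac_lowqual fraction of variants given failing read support.
#' @param class_probs named probabilities over consequence classes.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L, n_genes = 12L, n_samples = 16L,
                       exons_per_gene = c(3L, 12L),
                       exon_length_range = c(80L, 400L),
                       mean_depth = 400, depth_dispersion = 10,
                       lib_sd = 0.1, gc_bias_strength = 2,
                       boundary_falloff = 0.3, exon_effect_sd = 0.05,
                       pad5 = 35L, pad3 = 20L,
                       variant_burden = 5, burden_range = c(1L, 9L),
                       maf_novel_frac = 0.4, frac_offtarget = 0.06,
                       frac_lowqual = 0.06,
                       class_probs = c(missense = 0.50, synonymous = 0.25,
                                       splicing = 0.08, frameshift = 0.07,
                                       nonsense = 0.05, other = 0.05)) {
  stopifnot(seed == as.integer(seed), n_samples >= 2,
            boundary_falloff > 0, boundary_falloff <= 1,
            maf_novel_frac >= 0, maf_novel_frac <= 1,
            abs(sum(class_probs) - 1) < 1e-8)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a gene panel
#'
#' Deterministic for a given config seed. Genes get 1-60 exons (drawn
#' from the configured range), exon lengths uniform in the configured
#' range, random strand, per-exon GC fractions, and the standard
#' intronic padding applied.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return an \code{hc_panel} with a \code{gc} column.
#' @export
simulate_panel <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  rois <- list()
  cursor <- setNames(rep(10000L, 4), paste0("chr", 1:4))
  for (g in seq_len(cfg$n_genes)) {
    gene <- sprintf("GENE%02d", g)
    chrom <- paste0("chr", ((g - 1L) %% 4L) + 1L)
    n_ex <- if (cfg$exons_per_gene[1] == cfg$exons_per_gene[2])
      cfg$exons_per_gene[1]
    else sample(cfg$exons_per_gene[1]:cfg$exons_per_gene[2], 1)
    strand <- sample(c("+", "-"), 1)
    pos <- cursor[chrom]
    starts <- ends <- integer(n_ex)
    for (e in seq_len(n_ex)) {
      len <- sample(cfg$exon_length_range[1]:cfg$exon_length_range[2], 1)
      starts[e] <- pos
      ends[e] <- pos + len
      pos <- ends[e] + sample(300:3000, 1)  # intron
    }
    cursor[chrom] <- pos + 5000L  # intergenic gap
    ordinal <- if (strand == "-") rev(seq_len(n_ex)) else seq_len(n_ex)
    rois[[g]] <- data.frame(chrom = chrom, start = starts, end = ends,
                            gene = gene, transcript = paste0("TX_", gene),
                            exon = ordinal, strand = strand,
                            gc = round(runif(n_ex, 0.30, 0.70), 3),
                            stringsAsFactors = FALSE)
  }
  exons <- new_panel(do.call(rbind, rois), name = "simpanel")
  pad_exons(exons, pad5 = cfg$pad5, pad3 = cfg$pad3)
}

# depth multiplier per base of one ROI: ramps linearly from the
# boundary_falloff at the outer flank edges to 1.0 inside the exon
.falloff_vector <- function(len, pad_left, pad_right, floor) {
  f <- rep(1, len)
  if (pad_left > 0)
    f[seq_len(pad_left)] <- floor + (1 - floor) * (seq_len(pad_left) - 1) /
      pad_left
  if (pad_right > 0)
    f[len - seq_len(pad_right) + 1L] <- floor + (1 - floor) *
      (seq_len(pad_right) - 1) / pad_right
  f
}

.gc_factor <- function(gc, strength) pmax(0.1, 1 - strength * (gc - 0.45)^2)

.rdepth <- function(n, mu, size) {
  if (is.infinite(size)) rpois(n, mu) else rnbinom(n, size = size, mu = mu)
}

#' Simulate per-base coverage for a cohort
#'
#' Per-base depth is negative-binomial with mean
#' \code{mean_depth x library factor x GC factor x exon effect x falloff}.
#'
#' @param panel an \code{hc_panel} from \code{\link{simulate_panel}}
#'   (needs the \code{gc} column).
#' @param cfg a \code{\link{sim_config}}.
#' @return list of \code{depth_profile}s (samples \code{S01}...), each
#'   carrying its expected-depth vector for later event spiking.
#' @export
simulate_coverage <- function(panel, cfg = sim_config()) {
  set.seed(cfg$seed + 1L)
  gc <- if ("gc" %in% names(panel)) panel$gc else rep(0.45, nrow(panel))
  gcf <- .gc_factor(gc, cfg$gc_bias_strength)
  len <- panel$end - panel$start
  fall <- unlist(lapply(seq_len(nrow(panel)), function(i)
    .falloff_vector(len[i], panel$pad_left[i], panel$pad_right[i],
                    cfg$boundary_falloff)), use.names = FALSE)
  roi_of_base <- rep.int(seq_len(nrow(panel)), len)
  lapply(seq_len(cfg$n_samples), function(s) {
    sample_id <- sprintf("S%02d", s)
    lib <- exp(rnorm(1, 0, cfg$lib_sd))
    eff <- exp(rnorm(nrow(panel), 0, cfg$exon_effect_sd))
    mu <- cfg$mean_depth * lib * gcf[roi_of_base] * eff[roi_of_base] * fall
    depth <- .rdepth(length(mu), mu, cfg$depth_dispersion)
    new_depth_profile(sample_id, depth, panel, mu = mu)
  })
}

#' Spike copy-number events into simulated coverage
#'
#' Scales the expected depth over each event's exon span (0.5 for
#' heterozygous deletion, 0.02 for homozygous deletion, 1.5 for
#' duplication) and resamples those bases from the negative binomial.
#'
#' @param profiles output of \code{\link{simulate_coverage}}.
#' @param events data.frame with columns \code{sample}, \code{gene},
#'   \code{exon_first}, \code{exon_last}, \code{state}; no two events may
#'   overlap within one sample/gene.
#' @param cfg the \code{\link{sim_config}} used for the profiles.
#' @return list with \code{profiles} (modified) and \code{truth} (the
#'   events, with a \code{whole_gene} flag).
#' @export
spike_cnv <- function(profiles, events, cfg = sim_config()) {
  factors <- c(het_del = 0.5, hom_del = 0.02, dup = 1.5)
  if (is.null(events) || !nrow(events))
    return(list(profiles = profiles, truth = events))
  stopifnot(all(events$state %in% names(factors)))
  dup_key <- paste(events$sample, events$gene)
  if (anyDuplicated(dup_key))
    stop("overlapping events in one sample/gene: ",
         dup_key[duplicated(dup_key)][1])
  set.seed(cfg$seed + 2L)
  samples <- vapply(profiles, `[[`, character(1), "sample")
  panel <- profiles[[1]]$panel
  len <- panel$end - panel$start
  roi_of_base <- rep.int(seq_len(nrow(panel)), len)
  events$whole_gene <- FALSE
  for (i in seq_len(nrow(events))) {
    si <- match(events$sample[i], samples)
    if (is.na(si)) stop("event sample not simulated: ", events$sample[i])
    gi <- which(panel$gene == events$gene[i] &
                panel$exon >= events$exon_first[i] &
                panel$exon <= events$exon_last[i])
    if (!length(gi)) stop("event span matches no exon: row ", i)
    events$whole_gene[i] <-
      length(gi) == sum(panel$gene == events$gene[i])
    base_idx <- which(roi_of_base %in% gi)
    p <- profiles[[si]]
    p$mu[base_idx] <- p$mu[base_idx] * factors[[events$state[i]]]
    p$depth[base_idx] <- .rdepth(length(base_idx), p$mu[base_idx],
                                 cfg$depth_dispersion)
    profiles[[si]] <- p
  }
  list(profiles = profiles, truth = events)
}

#' Default condition gene sets for a simulated panel
#'
#' Splits the panel's genes into three clinical condition sets (HBOC,
#' LYNCH, NF) of near-equal size, mimicking clinically predefined lists.
#'
#' @param panel an \code{hc_panel}.
#' @return named list of \code{hc_geneset}s.
#' @export
default_genesets <- function(panel) {
  genes <- panel_genes(panel)
  grp <- rep(c("HBOC", "LYNCH", "NF"), length.out = length(genes))
  sets <- split(genes, grp)
  Map(geneset, names(sets), sets)
}

# Poisson rate whose [lo, hi]-truncated distribution has the target mean
# (the cohort's reported statistic is the mean of observed burdens, so the
# generator is calibrated on that scale, not on the raw rate)
.tpois_lambda <- function(target_mean, lo, hi) {
  tmean <- function(lambda) {
    k <- lo:hi
    p <- stats::dpois(k, lambda)
    sum(k * p) / sum(p)
  }
  stats::uniroot(function(l) tmean(l) - target_mean,
                 lower = 1e-3, upper = hi * 2, tol = 1e-9)$root
}

.rtrunc_pois <- function(n, lambda, lo, hi) {
  out <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rpois(1, lambda)
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

#' Simulate annotated variant tables with ground truth
#'
#' Per sample, a non-causal burden ~ Poisson(\code{variant_burden})
#' truncated to \code{burden_range}, plus exactly one causal
#' (disease-causing) variant in a gene of the sample's clinical
#' condition. Consequence classes follow \code{class_probs}; predictor
#' verdicts are correlated with class; MAFs come from a novel/log-uniform
#' mixture. Configured fractions of variants are placed off-target or
#' given failing read support so every downstream filter has work to do.
#'
#' @param panel an \code{hc_panel}.
#' @param cfg a \code{\link{sim_config}}.
#' @param genesets named list of condition gene sets (default:
#'   \code{\link{default_genesets}}).
#' @return list with \code{variants} (an \code{hc_variants} table over
#'   all samples), \code{conditions} (sample -> condition),
#'   \code{genesets}, and \code{truth} (burdens and the keys of causal,
#'   off-target and low-quality variants).
#' @export
simulate_variant_tables <- function(panel, cfg = sim_config(),
                                    genesets = default_genesets(panel)) {
  set.seed(cfg$seed + 3L)
  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  conditions <- setNames(rep(names(genesets), length.out = length(samples)),
                         samples)
  genes <- panel_genes(panel)
  # variant opportunity scales with a gene's captured bases
  gene_w <- as.numeric(tapply(panel$end - panel$start, panel$gene,
                              sum)[genes])
  damaging_prob <- c(nonsense = 0.92, frameshift = 0.92, splicing = 0.85,
                     missense = NA, synonymous = 0.05, other = 0.10)
  rows <- list()
  truth <- list(burden = setNames(integer(length(samples)), samples),
                causal_key = character(0), offtarget_key = character(0),
                lowqual_key = character(0))
  mk_variant <- function(sample_id, gene, causal, offtarget, lowqual) {
    gi <- which(panel$gene == gene)
    roi <- gi[sample.int(length(gi), 1)]
    pos <- if (offtarget) panel$end[roi] + sample(60:500, 1) + 1L
           else sample(panel$start[roi]:(panel$end[roi] - 1L), 1) + 1L
    cons <- if (causal)
      sample(c("nonsense", "frameshift", "splicing", "missense"), 1,
             prob = c(0.4, 0.3, 0.15, 0.15))
    else sample(names(cfg$class_probs), 1, prob = cfg$class_probs)
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    if (cons == "frameshift") alt <- paste0(ref, sample(c("A", "T"), 1))
    novel <- causal || runif(1) < cfg$maf_novel_frac
    base_maf <- if (novel) NA_real_ else 10^runif(1, -5, log10(0.05))
    dmg_p <- if (cons == "missense") {
      if (causal || runif(1) < 0.4) 0.85 else 0.12
    } else damaging_prob[[cons]]
    if (causal && cons != "missense") dmg_p <- 0.95
    preds <- ifelse(runif(5) < 0.05, NA_character_,
                    ifelse(runif(5) < dmg_p, "damaging", "neutral"))
    depth <- .rdepth(1, cfg$mean_depth, cfg$depth_dispersion)
    vaf <- if (lowqual) runif(1, 0.02, 0.08) else
      min(0.98, max(0.05, rnorm(1, 0.5, 0.06)))
    alt_reads <- max(if (lowqual) 0L else 2L, rbinom(1, depth, vaf))
    row <- data.frame(
      sample = sample_id, gene = gene, chrom = panel$chrom[roi],
      pos = pos, ref = ref, alt = alt, consequence = cons,
      zygosity = sample(c("het", "hom"), 1, prob = c(0.9, 0.1)),
      causal = causal,
      maf_1kg = base_maf,
      maf_exac = if (is.na(base_maf)) NA_real_ else
        min(1, base_maf * exp(rnorm(1, 0, 0.3))),
      pred_polyphen2_hdiv = preds[1], pred_polyphen2_hvar = preds[2],
      pred_sift = preds[3], pred_provean = preds[4],
      pred_mutationtaster = preds[5],
      depth = depth, alt_reads = alt_reads,
      vaf = alt_reads / max(depth, 1),
      alt_qual = if (lowqual) runif(1, 8, 14) else rnorm(1, 33, 2),
      alt_fwd = rbinom(1, alt_reads, 0.5), alt_rev = NA_real_,
      alt_mismatches = runif(1, 0.2, 1.5),
      read_pos_sd = runif(1, 0.15, 0.35) * 250,
      stringsAsFactors = FALSE)
    row$alt_rev <- row$alt_reads - row$alt_fwd
    row
  }
  lambda <- .tpois_lambda(cfg$variant_burden, cfg$burden_range[1],
                          cfg$burden_range[2])
  for (s in samples) {
    b <- .rtrunc_pois(1, lambda, cfg$burden_range[1], cfg$burden_range[2])
    truth$burden[s] <- b
    for (k in seq_len(b)) {
      offt <- runif(1) < cfg$frac_offtarget
      lowq <- !offt && runif(1) < cfg$frac_lowqual
      rows[[length(rows) + 1L]] <-
        mk_variant(s, sample(genes, 1, prob = gene_w), FALSE, offt, lowq)
    }
    causal_gene <- sample(genesets[[conditions[s]]]$genes, 1)
    cv <- mk_variant(s, causal_gene, TRUE, FALSE, FALSE)
    rows[[length(rows) + 1L]] <- cv
    truth$causal_key <- c(truth$causal_key, variant_key(cv))
  }
  df <- do.call(rbind, rows)
  v <- as_variants(df)
  truth$offtarget_key <- variant_key(df)[
    !duplicated(variant_key(df)) &
      vapply(seq_len(nrow(df)), function(i) {
        p0 <- df$pos[i] - 1L
        !any(panel$chrom == df$chrom[i] & panel$start <= p0 & panel$end > p0)
      }, logical(1))]
  truth$lowqual_key <- variant_key(df)[df$vaf < 0.10 | df$alt_qual < 15]
  list(variants = v, conditions = conditions, genesets = genesets,
       truth = truth)
}

#' Default spiked copy-number events for recovery studies
#'
#' One whole-gene heterozygous deletion, one two-exon heterozygous
#' deletion and one three-exon duplication, in three distinct samples,
#' placed on the first genes with enough exons.
#'
#' @param panel an \code{hc_panel}.
#' @param samples character vector of at least 3 sample ids.
#' @return event data.frame for \code{\link{spike_cnv}}.
#' @export
default_cnv_events <- function(panel, samples) {
  stopifnot(length(samples) >= 3)
  n_ex <- table(panel$gene)
  g_multi <- names(n_ex)[n_ex >= 4]
  if (length(g_multi) < 3) stop("panel too small for default event set")
  g1 <- g_multi[1]; g2 <- g_multi[2]; g3 <- g_multi[3]
  data.frame(
    sample = samples[1:3], gene = c(g1, g2, g3),
    exon_first = c(1L, 2L, 2L),
    exon_last = c(as.integer(n_ex[g1]), 3L, 4L),
    state = c("het_del", "het_del", "dup"),
    stringsAsFactors = FALSE)
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Emits the panel BED, one samtools-depth TSV per sample, gene-set
#' files, the annotated variant TSV and a truth JSON.
#'
#' @param dir output directory (created if needed).
#' @param cfg a \code{\link{sim_config}}.
#' @param cnv_events optional event data.frame for \code{\link{spike_cnv}}.
#' @return invisibly, a list with the in-memory objects.
#' @export
write_simulated_cohort <- function(dir, cfg = sim_config(),
                                   cnv_events = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_panel(cfg)
  profiles <- simulate_coverage(panel, cfg)
  truth_cnv <- NULL
  if (!is.null(cnv_events)) {
    sp <- spike_cnv(profiles, cnv_events, cfg)
    profiles <- sp$profiles
    truth_cnv <- sp$truth
  }
  write_panel(panel, file.path(dir, "panel.bed"))
  bm <- panel_base_map(panel)
  for (p in profiles) {
    df <- data.frame(chrom = bm$chrom, pos = bm$pos + 1L, depth = p$depth)
    df <- df[!duplicated(paste0(df$chrom, ":", df$pos)), ]
    write.table(df, file.path(dir, paste0(p$sample, ".depth.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  vt <- simulate_variant_tables(panel, cfg)
  write_variants(vt$variants, file.path(dir, "variants.tsv"))
  for (gs in vt$genesets)
    writeLines(gs$genes, file.path(dir, paste0("geneset_", gs$name, ".txt")))
  jsonlite::write_json(
    list(seed = cfg$seed, burden = as.list(vt$truth$burden),
         causal = vt$truth$causal_key, cnv = truth_cnv,
         conditions = as.list(vt$conditions)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(panel = panel, profiles = profiles, variants = vt,
                 cnv_truth = truth_cnv))
}
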