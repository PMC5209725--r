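# Annotated variant tables. One row per variant with columns:
#   sample, gene, chrom, pos (1-based), ref, alt, consequence
#   ("nonsense","frameshift","splicing","missense","synonymous","other","cnv"),
#   zygosity ("het","hom"), causal (logical),
#   maf_* (one column per population; NA = not in that database),
#   pred_* (predictor verdicts: "damaging"/"neutral"/NA = missing),
#   depth, alt_reads, vaf, alt_qual, alt_fwd, alt_rev, alt_mismatches,
#   read_pos_sd (read-support metrics; NA allowed).
# Every filter appends removed rows, tagged with the rule that removed
# them, to the "removed" attribute (audit contract).

PREDICTORS <- c("pred_polyphen2_hdiv", "pred_polyphen2_hvar", "pred_sift",
                "pred_provean", "pred_mutationtaster")

CONSEQUENCES <- c("nonsense", "frameshift", "splicing", "missense",
                  "synonymous", "other", "cnv")

.variant_columns <- function(n = 0) data.frame(
  sample = character(n), gene = character(n), chrom = character(n),
  pos = integer(n), ref = character(n), alt = character(n),
  consequence = character(n), zygosity = character(n), causal = logical(n),
  stringsAsFactors = FALSE)

as_variants <- function(df) {
  for (col in names(.variant_columns()))
    if (!col %in% names(df))
      stop("variant table is missing column: ", col)
  if (!all(df$consequence %in% CONSEQUENCES))
    stop("unknown consequence class: ",
         paste(setdiff(unique(df$consequence), CONSEQUENCES), collapse = ", "))
  for (p in PREDICTORS) if (!p %in% names(df)) df[[p]] <- NA_character_
  sup <- c("depth", "alt_reads", "vaf", "alt_qual", "alt_fwd", "alt_rev",
           "alt_mismatches", "read_pos_sd")
  for (p in sup) if (!p %in% names(df)) df[[p]] <- NA_real_
  bad <- !is.na(df$vaf) & (df$vaf < 0 | df$vaf > 1)
  if (any(bad)) stop("vaf outside [0,1] in variant row(s)")
  bad <- !is.na(df$alt_reads) & !is.na(df$depth) & df$alt_reads > df$depth
  if (any(bad)) stop("alt_reads exceeds depth in variant row(s)")
  mafs <- grep("^maf_", names(df), value = TRUE)
  for (mc in mafs) {
    v <- df[[mc]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop("population frequency outside [0,1] in column ", mc)
  }
  rownames(df) <- NULL
  structure(df, class = c("hc_variants", "data.frame"),
            removed = attr(df, "removed"))
}

.log_removed <- function(result, dropped, rule) {
  if (nrow(dropped)) {
    dropped$removed_by <- rule
    prev <- attr(result, "removed")
    attr(result, "removed") <- if (is.null(prev)) dropped else
      rbind(prev, dropped)
  }
  result
}

#' Audit trail of filtered-out variants
#' @param variants an \code{hc_variants} table after one or more filters.
#' @return data.frame of removed variants with a \code{removed_by} column,
#'   or an empty data.frame if nothing was removed.
#' @export
removed_variants <- function(variants) {
  r <- attr(variants, "removed")
  if (is.null(r)) cbind(.variant_columns(), removed_by = character(0)) else r
}

#' Read an annotated variant table (TSV)
#'
#' Tab-separated export with one row per variant. Required columns:
#' \code{gene, chrom, pos, ref, alt, consequence}. Recognised optional
#' columns: \code{zygosity, causal}, population frequencies
#' (\code{maf_*}), predictor verdicts (\code{pred_*}, values
#' damaging/neutral, empty = missing) and read-support metrics. Column
#' names can be remapped via \code{col_map} (names = file columns,
#' values = canonical names). Missing annotations stay missing (NA).
#'
#' @param path file path.
#' @param sample sample identifier applied to rows lacking a sample column.
#' @param col_map optional named character vector renaming file columns.
#' @param refseq optional reference sequence (named character per chrom)
#'   enabling full indel left-alignment via \code{\link{normalize_variant}}.
#' @return an \code{hc_variants} data.frame.
#' @export
read_variant_table <- function(path, sample = NULL, col_map = NULL,
                               refseq = NULL) {
  if (!file.exists(path)) stop("variant file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!is.null(col_map))
    names(df)[match(names(col_map), names(df))] <- unname(col_map)
  if (!"sample" %in% names(df)) {
    if (is.null(sample)) stop("no sample column and no sample= given")
    df$sample <- sample
  }
  req <- c("gene", "chrom", "pos", "ref", "alt", "consequence")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("variant file lacks column(s): ", paste(miss, collapse = ", "))
  if (!"zygosity" %in% names(df)) df$zygosity <- "het"
  if (!"causal" %in% names(df)) df$causal <- FALSE
  df$causal <- as.logical(df$causal)
  df$pos <- as.integer(df$pos)
  for (p in intersect(PREDICTORS, names(df)))
    df[[p]] <- tolower(as.character(df[[p]]))
  norm <- normalize_variant(df$pos, df$ref, df$alt,
                            chrom = df$chrom, refseq = refseq)
  df$pos <- norm$pos; df$ref <- norm$ref; df$alt <- norm$alt
  as_variants(df)
}

#' Read variants from a VCF file
#'
#' Thin ingestion path for VCF 4.x using the \pkg{vcfR} parser.
#' Annotation fields are pulled from INFO via \code{info_map}
#' (names = INFO keys, values = canonical variant-table columns).
#' Multi-allelic records must be pre-split.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param sample sample identifier for the resulting rows.
#' @param info_map named character vector mapping INFO keys to columns
#'   such as \code{gene}, \code{consequence}, \code{maf_*}, \code{pred_*}.
#' @param refseq optional reference for left-alignment.
#' @return an \code{hc_variants} data.frame.
#' @export
read_variant_vcf <- function(path, sample,
                             info_map = c(GENE = "gene", CSQ = "consequence"),
                             refseq = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF ingestion requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  df <- data.frame(sample = sample, chrom = fix$CHROM,
                   pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                   stringsAsFactors = FALSE)
  for (key in names(info_map)) {
    val <- vcfR::extract.info(v, element = key)
    col <- unname(info_map[key])
    df[[col]] <- if (grepl("^(maf_|vaf$|depth$|alt_)", col))
      suppressWarnings(as.numeric(val)) else val
  }
  if (!"gene" %in% names(df)) df$gene <- NA_character_
  if (!"consequence" %in% names(df)) df$consequence <- "other"
  df$consequence[is.na(df$consequence)] <- "other"
  df$zygosity <- "het"; df$causal <- FALSE
  norm <- normalize_variant(df$pos, df$ref, df$alt,
                            chrom = df$chrom, refseq = refseq)
  df$pos <- norm$pos; df$ref <- norm$ref; df$alt <- norm$alt
  as_variants(df)
}

#' Normalise variant representation
#'
#' Trims shared suffix then prefix bases from ref/alt (keeping one anchor
#' base for indels) and, when a reference sequence is supplied, left-shifts
#' indels to their canonical leftmost position. Guarantees that the same
#' physical change parsed from different representations yields one
#' (pos, ref, alt) triple.
#'
#' @param pos 1-based positions.
#' @param ref,alt allele strings.
#' @param chrom chromosome per variant (needed with \code{refseq}).
#' @param refseq named character vector of chromosome sequences, or NULL.
#' @return list with normalised \code{pos}, \code{ref}, \code{alt}.
#' @export
normalize_variant <- function(pos, ref, alt, chrom = NULL, refseq = NULL) {
  pos <- as.integer(pos); ref <- toupper(ref); alt <- toupper(alt)
  n <- length(pos)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    if (is.na(r) || is.na(a)) next
    # trim common suffix
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1); a <- substr(a, 1, nchar(a) - 1)
    }
    # trim common prefix, keeping >=1 base each
    while (nchar(r) > 1 && nchar(a) > 1 && substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r)); a <- substr(a, 2, nchar(a)); p <- p + 1L
    }
    if (!is.null(refseq) && !is.null(chrom) && chrom[i] %in% names(refseq) &&
        nchar(r) != nchar(a)) {
      seqc <- refseq[[chrom[i]]]
      if (substr(seqc, p, p + nchar(r) - 1L) != r)
        stop("reference mismatch at ", chrom[i], ":", p,
             " (expected ", r, ")")
      # canonical left-alignment: right-trim shared bases, extending to
      # the left whenever an allele empties, then left-trim to the anchor
      repeat {
        if (nchar(r) > 0 && nchar(a) > 0 &&
            substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
          r <- substr(r, 1, nchar(r) - 1L)
          a <- substr(a, 1, nchar(a) - 1L)
        } else if ((nchar(r) == 0 || nchar(a) == 0) && p > 1L) {
          p <- p - 1L
          prev <- substr(seqc, p, p)
          r <- paste0(prev, r)
          a <- paste0(prev, a)
        } else break
      }
      while (nchar(r) > 1 && nchar(a) > 1 &&
             substr(r, 1, 1) == substr(a, 1, 1)) {
        r <- substr(r, 2, nchar(r)); a <- substr(a, 2, nchar(a)); p <- p + 1L
      }
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Variant-caller sanity-filter configuration
#'
#' Defaults mirror the locked parameters of the upstream caller
#' (minimum coverage 10, at least 2 supporting reads, mean base quality
#' 15, variant allele fraction 0.10) so ingested tables are held to the
#' same contract; the rarity cutoff (1\%) is carried alongside.
#'
#' @param maf_cutoff population-frequency rarity cutoff (strict `<`).
#' @param min_depth minimum total depth at the site.
#' @param min_alt_reads minimum reads supporting the alternative allele.
#' @param min_avg_qual minimum mean base quality of alt-supporting bases.
#' @param min_vaf minimum variant allele fraction (inclusive).
#' @return a \code{filter_config} list.
#' @export
filter_config <- function(maf_cutoff = 0.01, min_depth = 10,
                          min_alt_reads = 2, min_avg_qual = 15,
                          min_vaf = 0.10) {
  stopifnot(maf_cutoff > 0, maf_cutoff < 1, min_depth >= 0,
            min_alt_reads >= 0, min_avg_qual >= 0, min_vaf >= 0)
  structure(list(maf_cutoff = maf_cutoff, min_depth = min_depth,
                 min_alt_reads = min_alt_reads, min_avg_qual = min_avg_qual,
                 min_vaf = min_vaf), class = "filter_config")
}

#' Read-support sanity filter
#'
#' Keeps variants meeting the caller's locked support thresholds:
#' depth >= min_depth, alt reads >= min_alt_reads, mean alt base quality
#' >= min_avg_qual, VAF >= min_vaf (all inclusive on the keep side).
#' A metric that is absent (NA) does not apply its test. CNV rows are
#' exempt (no read support by construction).
#'
#' @param variants an \code{hc_variants} table.
#' @param config a \code{\link{filter_config}}.
#' @return the filtered table; removed rows in \code{\link{removed_variants}}.
#' @export
sanity_filter <- function(variants, config = filter_config()) {
  v <- variants
  test <- function(x, thr) is.na(x) | x >= thr
  keep <- v$consequence == "cnv" |
    (test(v$depth, config$min_depth) &
     test(v$alt_reads, config$min_alt_reads) &
     test(v$alt_qual, config$min_avg_qual) &
     test(v$vaf, config$min_vaf))
  out <- as_variants(as.data.frame(v)[keep, , drop = FALSE])
  attr(out, "removed") <- attr(variants, "removed")
  .log_removed(out, as.data.frame(v)[!keep, , drop = FALSE], "sanity")
}

#' Restrict variants to a clinical gene set
#' @param variants an \code{hc_variants} table.
#' @param gset an \code{hc_geneset}.
#' @return filtered table (order preserved); removals audited.
#' @export
filter_by_geneset <- function(variants, gset) {
  stopifnot(inherits(gset, "hc_geneset"))
  keep <- variants$gene %in% gset$genes
  out <- as_variants(as.data.frame(variants)[keep, , drop = FALSE])
  attr(out, "removed") <- attr(variants, "removed")
  .log_removed(out, as.data.frame(variants)[!keep, , drop = FALSE], "geneset")
}

#' Restrict variants to panel regions of interest
#'
#' A variant is kept iff its 0-based position (\code{pos - 1}) falls in
#' some ROI interval (half-open: start inclusive, end exclusive). CNV
#' rows are kept (their span is exon-derived by construction).
#'
#' @param variants an \code{hc_variants} table.
#' @param panel an \code{hc_panel}, ideally merged per gene.
#' @return filtered table; removals audited.
#' @export
filter_by_region <- function(variants, panel) {
  keep <- variants$consequence == "cnv"
  for (ch in unique(variants$chrom)) {
    vi <- which(variants$chrom == ch & !keep)
    pi <- which(panel$chrom == ch)
    if (!length(vi) || !length(pi)) next
    # both sides expressed as 0-based positions in closed IRanges coords
    q <- IRanges::IRanges(start = variants$pos[vi] - 1L, width = 1L)
    s <- IRanges::IRanges(start = panel$start[pi], end = panel$end[pi] - 1L)
    hit <- IRanges::overlapsAny(q, s)
    keep[vi[hit]] <- TRUE
  }
  out <- as_variants(as.data.frame(variants)[keep, , drop = FALSE])
  attr(out, "removed") <- attr(variants, "removed")
  .log_removed(out, as.data.frame(variants)[!keep, , drop = FALSE], "region")
}

#' Rare-variant filter
#'
#' Keeps variants whose minor allele frequency is strictly below the
#' cutoff (default 1\%) in every population with a recorded frequency.
#' Variants absent from all databases (no MAF at all) are kept: absence
#' of a record cannot make a variant common.
#'
#' @param variants an \code{hc_variants} table with \code{maf_*} columns.
#' @param maf_cutoff rarity cutoff, strict inequality (default 0.01).
#' @return filtered table; removals audited.
#' @export
rare_filter <- function(variants, maf_cutoff = 0.01) {
  mafs <- grep("^maf_", names(variants), value = TRUE)
  keep <- if (!length(mafs)) rep(TRUE, nrow(variants)) else {
    m <- as.matrix(as.data.frame(variants)[, mafs, drop = FALSE])
    apply(m, 1, function(x) all(is.na(x) | x < maf_cutoff))
  }
  out <- as_variants(as.data.frame(variants)[keep, , drop = FALSE])
  attr(out, "removed") <- attr(variants, "removed")
  .log_removed(out, as.data.frame(variants)[!keep, , drop = FALSE], "maf")
}

#' Consensus of in-silico pathogenicity predictors
#'
#' Combines the five predictor verdicts (PolyPhen2 HDIV/HVAR, SIFT,
#' PROVEAN, MutationTaster) under one of two policies used at different
#' points of the workflow: the \emph{landscape} policy labels a variant
#' \code{neutral} only when more than 3 predictors (i.e. at least 4 of 5)
#' call it neutral, otherwise \code{possibly_damaging}; the \emph{report}
#' policy labels it \code{deleterious} when 3 or more predictors call it
#' damaging, otherwise \code{not_deleterious}. Missing verdicts count
#' toward neither threshold. The two policies intentionally disagree for
#' e.g. 3 neutral / 2 damaging.
#'
#' @param variants an \code{hc_variants} table (or any data.frame with the
#'   \code{pred_*} columns).
#' @param policy \code{"landscape"} or \code{"report"}.
#' @return data.frame with \code{label}, \code{n_neutral}, \code{n_damaging},
#'   \code{n_missing} (rows parallel to input).
#' @export
consensus_prediction <- function(variants, policy = c("landscape", "report")) {
  policy <- match.arg(policy)
  pm <- as.matrix(as.data.frame(variants)[, PREDICTORS, drop = FALSE])
  n_neutral <- rowSums(pm == "neutral", na.rm = TRUE)
  n_damaging <- rowSums(pm == "damaging", na.rm = TRUE)
  n_missing <- length(PREDICTORS) - n_neutral - n_damaging
  label <- if (policy == "landscape")
    ifelse(n_neutral > 3, "neutral", "possibly_damaging")
  else
    ifelse(n_damaging >= 3, "deleterious", "not_deleterious")
  data.frame(label = label, n_neutral = as.integer(n_neutral),
             n_damaging = as.integer(n_damaging),
             n_missing = as.integer(n_missing),
             stringsAsFactors = FALSE, row.names = NULL)
}

# severity classes in decreasing order; missense is split by the
# landscape consensus into possibly_damaging vs neutral
SEVERITY_ORDER <- c("cnv", "nonsense", "frameshift", "splicing",
                    "missense_possibly_damaging", "missense_neutral",
                    "synonymous", "other")

#' Display class of a variant (consequence, with missense split)
#' @param variants an \code{hc_variants} table.
#' @return character vector of display classes (see \code{SEVERITY_ORDER}).
#' @export
display_class <- function(variants) {
  cls <- variants$consequence
  mis <- which(cls == "missense")
  if (length(mis)) {
    verdict <- consensus_prediction(
      as.data.frame(variants)[mis, , drop = FALSE], "landscape")$label
    cls[mis] <- paste0("missense_", verdict)
  }
  cls
}

#' Most damaging variant of a group
#'
#' Selects the single most severe variant among variants sharing one
#' (sample, gene) cell, under the fixed severity order
#' cnv > nonsense > frameshift > splicing > missense (possibly damaging)
#' > missense (neutral) > synonymous > other; ties broken by smaller
#' genomic position. Input order does not matter.
#'
#' @param variants non-empty \code{hc_variants} subset.
#' @return the selected single-row data.frame.
#' @export
most_damaging <- function(variants) {
  if (!nrow(variants)) stop("most_damaging on empty variant group")
  rank <- match(display_class(variants), SEVERITY_ORDER)
  ord <- order(rank, variants$pos)
  as.data.frame(variants)[ord[1], , drop = FALSE]
}

#' Variant quality-indicator flags
#'
#' Heuristic warnings that guide orthogonal validation of a call:
#' \code{low_vaf} (VAF < 0.2), \code{strand_bias} (>= 5 alt reads, all on
#' one strand), \code{low_base_quality} (mean alt base quality < 20),
#' \code{mismatch_rich} (mean mismatches in alt reads > 3),
#' \code{positional_clustering} (alt read-position sd < 5\% of read
#' length). Absent metrics yield no flag.
#'
#' @param variants an \code{hc_variants} table.
#' @param low_vaf,min_qual,max_mismatches thresholds as documented.
#' @param strand_min_reads minimum alt reads before strand bias is flagged.
#' @param pos_sd_frac positional-clustering threshold as a fraction of
#'   \code{read_length}.
#' @param read_length nominal read length in bases.
#' @return character vector, per variant, of comma-joined flags ("" = clean).
#' @export
quality_flags <- function(variants, low_vaf = 0.2, strand_min_reads = 5,
                          min_qual = 20, max_mismatches = 3,
                          pos_sd_frac = 0.05, read_length = 250) {
  v <- as.data.frame(variants)
  n <- nrow(v)
  flags <- vector("list", n)
  add <- function(cond, lab) {
    cond[is.na(cond)] <- FALSE
    for (i in which(cond)) flags[[i]] <<- c(flags[[i]], lab)
  }
  add(v$vaf < low_vaf, "low_vaf")
  one_strand <- (v$alt_fwd == 0 | v$alt_rev == 0) &
    (v$alt_fwd + v$alt_rev >= strand_min_reads)
  add(one_strand, "strand_bias")
  add(v$alt_qual < min_qual, "low_base_quality")
  add(v$alt_mismatches > max_mismatches, "mismatch_rich")
  add(v$read_pos_sd < pos_sd_frac * read_length, "positional_clustering")
  vapply(flags, function(f) paste(f, collapse = ","), character(1))
}

#' Write a variant table (with audit column) as TSV
#' @param variants an \code{hc_variants} table.
#' @param path output path.
#' @param removed_path optional path for the removed-variant audit TSV.
#' @return \code{path}, invisibly.
#' @export
write_variants <- function(variants, path, removed_path = NULL) {
  write.table(as.data.frame(variants), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(removed_path))
    write.table(removed_variants(variants), removed_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}
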