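# Per-base depth over panel ROIs. A depth_profile stores one integer depth
# per ROI base, in panel row order then ascending position, together with
# the ROI index of each base. Bases absent from the input file are 0.

#' Enumerate the bases of a panel
#'
#' @param panel an \code{hc_panel}.
#' @return a list with parallel vectors \code{chrom}, \code{pos} (0-based)
#'   and \code{roi} (row index into the panel), one element per ROI base.
#' @export
panel_base_map <- function(panel) {
  len <- panel$end - panel$start
  roi <- rep.int(seq_len(nrow(panel)), len)
  pos <- unlist(lapply(seq_len(nrow(panel)),
                       function(i) seq.int(panel$start[i], panel$end[i] - 1L)),
                use.names = FALSE)
  list(chrom = panel$chrom[roi], pos = pos, roi = roi, n = sum(len))
}

new_depth_profile <- function(sample, depth, panel, mu = NULL) {
  bm <- panel_base_map(panel)
  stopifnot(length(depth) == bm$n)
  structure(list(sample = sample, depth = as.numeric(depth),
                 panel = panel, base_map = bm, mu = mu),
            class = "depth_profile")
}

#' Read per-base depths for one sample
#'
#' Accepts the \code{samtools depth} dialect (chrom, 1-based position,
#' depth; 3 columns) or bedGraph (chrom, 0-based start, end, depth;
#' 4 columns). Only panel ROI bases are retained; panel bases absent from
#' the file get depth 0. Lines on chromosomes not in the panel are skipped
#' with a warning.
#'
#' @param path depth file path.
#' @param panel an \code{hc_panel}.
#' @param sample sample identifier (default: file name).
#' @param format \code{"auto"} (by column count), \code{"depth"} or
#'   \code{"bedgraph"}.
#' @return a \code{depth_profile}.
#' @export
read_depths <- function(path, panel, sample = basename(path),
                        format = c("auto", "depth", "bedgraph")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("depth file not found: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (format == "auto")
    format <- if (ncol(df) >= 4) "bedgraph" else "depth"
  bm <- panel_base_map(panel)
  depth <- numeric(bm$n)
  unknown <- setdiff(unique(df[[1]]), unique(panel$chrom))
  if (length(unknown)) {
    warning("skipping depth lines on chromosome(s) not in panel: ",
            paste(unknown, collapse = ", "))
    df <- df[df[[1]] %in% panel$chrom, , drop = FALSE]
  }
  if (format == "depth") {
    d <- as.numeric(df[[3]])
    if (any(d < 0)) stop("negative depth value in ", path)
    key_file <- paste0(df[[1]], ":", as.integer(df[[2]]) - 1L)
  } else {
    d0 <- as.numeric(df[[4]])
    if (any(d0 < 0)) stop("negative depth value in ", path)
    runlen <- as.integer(df[[3]]) - as.integer(df[[2]])
    if (any(runlen < 1)) stop("empty bedGraph interval in ", path)
    d <- rep.int(d0, runlen)
    pos <- unlist(lapply(seq_len(nrow(df)), function(i)
      seq.int(df[[2]][i], df[[3]][i] - 1L)), use.names = FALSE)
    key_file <- paste0(rep.int(df[[1]], runlen), ":", pos)
  }
  key_panel <- paste0(bm$chrom, ":", bm$pos)
  hit <- match(key_panel, key_file)
  depth[!is.na(hit)] <- d[hit[!is.na(hit)]]
  new_depth_profile(sample, depth, panel)
}

# unique-base mask: bases covered by ROIs of more than one gene (or
# overlapping ROIs generally) are counted once for global metrics
.unique_base_mask <- function(bm) !duplicated(paste0(bm$chrom, ":", bm$pos))

#' Summarise diagnostic coverage for one sample
#'
#' Computes the three panel-level quality metrics over unique ROI bases:
#' mean depth; C30, the fraction of bases at or above \code{min_depth}
#' (default 30x, the diagnostic-quality threshold); and uniformity, the
#' fraction of bases whose depth lies within \code{uniformity_window}
#' (default +/-20\%, both endpoints inclusive) of the mean. Per-ROI mean
#' depths are also returned for downstream copy-number analysis.
#'
#' @param profile a \code{depth_profile}.
#' @param panel an \code{hc_panel} (defaults to the profile's panel).
#' @param min_depth integer depth threshold for C30-style metric.
#' @param uniformity_window half-width of the uniformity band as a
#'   fraction of the mean.
#' @return a \code{coverage_summary} list with fields \code{sample},
#'   \code{mean_depth}, \code{c30}, \code{uniformity}, \code{per_exon_mean},
#'   \code{n_bases}.
#' @export
summarize_coverage <- function(profile, panel = profile$panel,
                               min_depth = 30L, uniformity_window = 0.2) {
  bm <- profile$base_map
  if (bm$n == 0) stop("panel has zero ROI bases")
  d <- profile$depth
  uniq <- .unique_base_mask(bm)
  du <- d[uniq]
  m <- mean(du)
  c30 <- mean(du >= min_depth)
  unif <- mean(du >= (1 - uniformity_window) * m &
               du <= (1 + uniformity_window) * m)
  per_exon <- vapply(split(d, factor(bm$roi, levels = seq_len(nrow(panel)))),
                     mean, numeric(1))
  names(per_exon) <- paste0(panel$gene, "_e",
                            ifelse(is.na(panel$exon), seq_len(nrow(panel)),
                                   panel$exon))
  structure(list(sample = profile$sample, mean_depth = m, c30 = c30,
                 uniformity = unif, per_exon_mean = per_exon,
                 n_bases = length(du)),
            class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf(
    "<coverage_summary> sample %s: mean depth %.1f, C30 %.1f%%, uniformity %.1f%% (%d bases)\n",
    x$sample, x$mean_depth, 100 * x$c30, 100 * x$uniformity, x$n_bases))
  invisible(x)
}

#' Write a coverage summary as one-row TSV and JSON
#'
#' @param summary a \code{coverage_summary}.
#' @param path_tsv,path_json output paths (either may be \code{NULL}).
#' @return invisibly, the one-row data.frame written.
#' @export
write_coverage_summary <- function(summary, path_tsv = NULL, path_json = NULL) {
  row <- data.frame(sample = summary$sample,
                    mean_depth = summary$mean_depth,
                    c30 = summary$c30, uniformity = summary$uniformity,
                    n_bases = summary$n_bases)
  if (!is.null(path_tsv))
    write.table(row, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(c(as.list(row),
                           list(per_exon_mean = summary$per_exon_mean)),
                         path_json, auto_unbox = TRUE, digits = NA)
  invisible(row)
}

#' Find ROIs requiring Sanger fallback
#'
#' Applies the diagnostic rule that any analysed ROI with a single base
#' below the minimum depth (default 30x) must be re-sequenced by Sanger.
#' Only ROIs of genes in the clinical gene set are considered.
#'
#' @param profile a \code{depth_profile}.
#' @param panel an \code{hc_panel} (defaults to the profile's panel).
#' @param gset an \code{hc_geneset}, or \code{NULL} for all panel genes.
#' @param min_depth minimum acceptable per-base depth.
#' @return a \code{gap_report} data.frame with one row per failing ROI:
#'   sample, gene, chrom, start, end, exon, min_depth, n_below.
#' @export
find_sanger_regions <- function(profile, panel = profile$panel, gset = NULL,
                                min_depth = 30L) {
  bm <- profile$base_map
  keep_roi <- if (is.null(gset)) rep(TRUE, nrow(panel)) else {
    unknown <- setdiff(gset$genes, panel$gene)
    if (length(unknown))
      stop("gene(s) not on panel: ", paste(unknown, collapse = ", "))
    panel$gene %in% gset$genes
  }
  f <- factor(bm$roi, levels = seq_len(nrow(panel)))
  roi_min <- vapply(split(profile$depth, f), min, numeric(1))
  roi_below <- vapply(split(profile$depth < min_depth, f), sum, numeric(1))
  fail <- which(keep_roi & roi_min < min_depth)
  out <- data.frame(sample = rep(profile$sample, length(fail)),
                    gene = panel$gene[fail], chrom = panel$chrom[fail],
                    start = panel$start[fail], end = panel$end[fail],
                    exon = panel$exon[fail],
                    min_depth = roi_min[fail],
                    n_below = as.integer(roi_below[fail]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("gap_report", "data.frame"),
            threshold = min_depth)
}

#' Write a gap report as TSV
#' @param report a \code{gap_report}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gap_report <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
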