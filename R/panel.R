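#' @importFrom stats median mad qbeta rnorm rpois rnbinom runif rbinom setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

# Panel container: a data.frame of ROIs (one row per region of interest)
# with columns chrom, start, end (0-based half-open), gene, transcript,
# exon (ordinal in transcription order), strand, pad_left, pad_right and
# optionally gc. Class "hc_panel"; panel name/version kept as an attribute.

new_panel <- function(df, name = "panel") {
  required <- c("chrom", "start", "end", "gene")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("panel is missing required column(s): ", paste(missing, collapse = ", "))
  if (!"transcript" %in% names(df)) df$transcript <- ""
  if (!"exon" %in% names(df)) df$exon <- NA_integer_
  if (!"strand" %in% names(df)) df$strand <- "+"
  if (!"pad_left" %in% names(df)) df$pad_left <- 0L
  if (!"pad_right" %in% names(df)) df$pad_right <- 0L
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$exon <- as.integer(df$exon)
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("empty or inverted interval (start >= end) in ROI row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (any(df$start < 0)) stop("negative start coordinate in panel")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("hc_panel", "data.frame"), panel_name = name)
}

#' Read a panel definition from a BED-like file
#'
#' The file is tab-separated with 0-based half-open coordinates and
#' columns \code{chrom, start, end, gene} plus optional columns 5-7
#' \code{transcript, exon, strand}. Lines starting with \code{#},
#' \code{track} or \code{browser} are skipped.
#'
#' @param path path to the interval file.
#' @param name panel name/version label attached to the result.
#' @return an \code{hc_panel} data.frame of ROIs sorted by (chrom, start).
#' @export
load_panel <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) stop("panel file has no interval lines: ", path)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 4))
    stop("malformed panel line ", idx[which(n < 4)[1]],
         ": expected at least 4 tab-separated fields")
  get <- function(i, default) vapply(fields, function(f)
    if (length(f) >= i && nzchar(f[i])) f[i] else default, character(1))
  start <- suppressWarnings(as.integer(get(2, NA_character_)))
  end <- suppressWarnings(as.integer(get(3, NA_character_)))
  if (anyNA(start) || anyNA(end))
    stop("malformed panel line ", idx[which(is.na(start) | is.na(end))[1]],
         ": non-integer coordinate")
  df <- data.frame(
    chrom = get(1, NA_character_), start = start, end = end,
    gene = get(4, NA_character_), transcript = get(5, ""),
    exon = suppressWarnings(as.integer(get(6, NA_character_))),
    strand = get(7, "+"), stringsAsFactors = FALSE)
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("validation error at panel line ", idx[bad[1]],
         ": start >= end (empty interval)")
  new_panel(df, name = name)
}

#' Write a panel to a BED-like file
#'
#' @param panel an \code{hc_panel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)[, c("chrom", "start", "end", "gene",
                                 "transcript", "exon", "strand")]
  df$exon[is.na(df$exon)] <- ""
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' List of genes on a panel
#' @param panel an \code{hc_panel}.
#' @return sorted character vector of gene symbols.
#' @export
panel_genes <- function(panel) sort(unique(panel$gene))

#' Pad exons into diagnostic regions of interest
#'
#' Extends each exon into its flanking introns so that splice regions are
#' captured: by default 35 bases on the splice-acceptor (upstream) side
#' and 20 on the donor (downstream) side, in transcription orientation.
#' For a plus-strand exon \code{[s, e)} this yields \code{[s - pad5, e + pad3)};
#' for a minus-strand exon \code{[s - pad3, e + pad5)}. With
#' \code{strand_aware = FALSE} the genomic-left flank always receives
#' \code{pad5} and the genomic-right flank \code{pad3}, regardless of strand.
#' Padding that would cross position 0 is clamped with a warning.
#'
#' @param exons an \code{hc_panel} (or ROI data.frame) of unpadded exons.
#' @param pad5 intronic bases on the upstream/acceptor side (default 35).
#' @param pad3 intronic bases on the downstream/donor side (default 20).
#' @param strand_aware interpret pads in transcription orientation (default).
#' @return the input with intervals widened and \code{pad_left}/\code{pad_right}
#'   recording the genomic-left/right padding actually applied.
#' @export
pad_exons <- function(exons, pad5 = 35L, pad3 = 20L, strand_aware = TRUE) {
  # negative pads shrink the intervals (undoing a previous padding)
  df <- as.data.frame(exons)
  minus <- df$strand == "-"
  left <- ifelse(strand_aware & minus, pad3, pad5)
  right <- ifelse(strand_aware & minus, pad5, pad3)
  new_start <- df$start - left
  if (any(new_start < 0)) {
    warning("padding crosses position 0 for ", sum(new_start < 0),
            " ROI(s); clamped to 0")
    left <- ifelse(new_start < 0, df$start, left)
    new_start <- pmax(new_start, 0L)
  }
  df$start <- as.integer(new_start)
  df$end <- as.integer(df$end + right)
  df$pad_left <- as.integer(left)
  df$pad_right <- as.integer(right)
  new_panel(df, name = attr(exons, "panel_name") %||% "panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge overlapping ROIs per gene
#'
#' Unions overlapping or bookended ROIs of the same gene (as arise from
#' multiple translated isoforms) and renumbers exon ordinals consecutively
#' along the transcription direction. Total covered bases per gene are
#' unchanged. Idempotent.
#'
#' @param panel an \code{hc_panel}.
#' @return an \code{hc_panel} with at most one ROI covering any base per gene.
#' @export
merge_rois <- function(panel) {
  pieces <- lapply(split(as.data.frame(panel), panel$gene), function(g) {
    merged_all <- lapply(split(g, g$chrom), function(gc) {
      ir <- IRanges::reduce(IRanges::IRanges(start = gc$start + 1L, end = gc$end))
      strand <- names(sort(table(gc$strand), decreasing = TRUE))[1]
      data.frame(chrom = gc$chrom[1],
                 start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
                 gene = gc$gene[1], transcript = "",
                 exon = NA_integer_, strand = strand,
                 pad_left = min(gc$pad_left), pad_right = min(gc$pad_right),
                 stringsAsFactors = FALSE)
    })
    m <- do.call(rbind, merged_all)
    m <- m[order(m$chrom, m$start), , drop = FALSE]
    # ordinal follows transcription: minus-strand genes count from the right
    m$exon <- if (m$strand[1] == "-") rev(seq_len(nrow(m))) else seq_len(nrow(m))
    m
  })
  out <- do.call(rbind, pieces)
  if ("gc" %in% names(panel)) {
    # carry mean GC of constituent exons onto merged ROIs where computable
    key <- paste(out$chrom, out$gene)
    out$gc <- NA_real_
    for (i in seq_len(nrow(out))) {
      hit <- panel$gene == out$gene[i] & panel$chrom == out$chrom[i] &
        panel$start < out$end[i] & panel$end > out$start[i]
      if (any(hit)) out$gc[i] <- mean(panel$gc[hit], na.rm = TRUE)
    }
  }
  new_panel(out, name = attr(panel, "panel_name") %||% "panel")
}

#' Construct a clinical gene set
#'
#' A named set of genes with clinical utility for one hereditary-cancer
#' condition (e.g. HBOC, Lynch, FAP, NF), used to restrict analysis.
#'
#' @param name condition label.
#' @param genes character vector of gene symbols (non-empty, deduplicated).
#' @return an \code{hc_geneset} object.
#' @export
geneset <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("gene set '", name, "' is empty")
  structure(list(name = name, genes = genes), class = "hc_geneset")
}

#' Read a clinical gene set from a plain-text file
#'
#' One gene symbol per line; \code{#} starts a comment.
#'
#' @param path file path.
#' @param name set name (defaults to the file name without extension).
#' @return an \code{hc_geneset}.
#' @export
load_geneset <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("gene set file not found: ", path)
  lines <- sub("#.*$", "", readLines(path))
  genes <- trimws(lines)
  geneset(name, genes[nzchar(genes)])
}

#' Restrict a panel to the genes of a clinical set
#'
#' @param panel an \code{hc_panel}.
#' @param gset an \code{hc_geneset}; every gene must be on the panel.
#' @return the panel restricted to ROIs of the set's genes.
#' @export
select_genes <- function(panel, gset) {
  stopifnot(inherits(gset, "hc_geneset"))
  unknown <- setdiff(gset$genes, panel$gene)
  if (length(unknown))
    stop("gene(s) not on panel: ", paste(unknown, collapse = ", "))
  out <- as.data.frame(panel)[panel$gene %in% gset$genes, , drop = FALSE]
  new_panel(out, name = attr(panel, "panel_name") %||% "panel")
}

#' @export
print.hc_panel <- function(x, ...) {
  cat(sprintf("<hc_panel '%s'> %d ROIs, %d genes, %s bases\n",
              attr(x, "panel_name"), nrow(x), length(unique(x$gene)),
              format(sum(x$end - x$start), big.mark = ",")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' @export
print.hc_geneset <- function(x, ...) {
  cat(sprintf("<hc_geneset '%s'> %d genes: %s\n", x$name, length(x$genes),
              paste(utils::head(x$genes, 8), collapse = ", ")))
  invisible(x)
}
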