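# Rare-variant landscape: a gene x sample matrix of retained variants.
# Each non-empty cell shows the class of the most damaging variant in
# that gene for that sample; disease-causing mutations are flagged and
# excluded from the gene-ordering totals.

#' Build the gene x sample variant landscape
#'
#' @param variants rare-filtered \code{hc_variants} (missense rows are
#'   split into neutral / possibly damaging via the landscape consensus).
#' @param conditions optional named character vector mapping sample ->
#'   clinical condition; unlabelled samples go to an "unknown" group with
#'   a warning.
#' @return a \code{landscape_matrix}: list with \code{cells} (gene,
#'   sample, n_variants, n_causal, display_class, causal_present),
#'   \code{genes} (ordered by descending non-causal total, ties
#'   alphabetical), \code{samples} (grouped by condition, then descending
#'   total variants, ties alphabetical), \code{conditions}.
#' @export
build_landscape <- function(variants, conditions = NULL) {
  v <- as.data.frame(variants)
  v$display_class <- display_class(variants)
  samples <- sort(unique(v$sample))
  if (is.null(conditions)) conditions <- setNames(rep("all", length(samples)),
                                                  samples)
  missing <- setdiff(samples, names(conditions))
  if (length(missing)) {
    warning("sample(s) without condition label assigned 'unknown': ",
            paste(missing, collapse = ", "))
    conditions[missing] <- "unknown"
  }
  cell_of <- split(seq_len(nrow(v)), paste(v$gene, v$sample, sep = "\r"))
  cells <- do.call(rbind, lapply(cell_of, function(idx) {
    vi <- v[idx, , drop = FALSE]
    top <- most_damaging(structure(vi, class = c("hc_variants", "data.frame")))
    data.frame(gene = vi$gene[1], sample = vi$sample[1],
               n_variants = nrow(vi), n_causal = sum(vi$causal),
               display_class = display_class(
                 structure(top, class = c("hc_variants", "data.frame"))),
               causal_present = any(vi$causal),
               stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL
  gene_tot <- tapply(cells$n_variants - cells$n_causal, cells$gene, sum)
  genes <- names(gene_tot)[order(-gene_tot, names(gene_tot))]
  samp_tot <- tapply(cells$n_variants, cells$sample, sum)
  samp_tot <- samp_tot[samples]
  ord <- order(conditions[samples], -samp_tot, samples)
  structure(list(cells = cells, genes = genes, samples = samples[ord],
                 conditions = conditions[samples[ord]]),
            class = "landscape_matrix")
}

#' Summary statistics of a variant landscape
#'
#' @param m a \code{landscape_matrix}.
#' @return a \code{landscape_stats} list:
#'   \code{per_sample_counts} (all retained variants per sample),
#'   \code{per_sample_noncausal}, \code{range} and \code{mean_per_sample}
#'   (over per-sample totals), \code{per_gene_totals} (non-causal, in gene
#'   order), \code{top_decile_share} (fraction of non-causal variants in
#'   the top ceil(10\%) of genes with >= 1 non-causal variant),
#'   \code{multihit} = (number of gene-sample pairs with >= 2 variants,
#'   number of variants in those pairs).
#' @export
landscape_stats <- function(m) {
  if (!nrow(m$cells)) stop("empty landscape")
  cells <- m$cells
  per_sample <- tapply(cells$n_variants, cells$sample, sum)
  per_sample <- setNames(as.integer(per_sample)[match(m$samples,
                                                      names(per_sample))],
                         m$samples)
  per_sample[is.na(per_sample)] <- 0L
  nc <- tapply(cells$n_variants - cells$n_causal, cells$sample, sum)
  per_sample_nc <- setNames(as.integer(nc)[match(m$samples, names(nc))],
                            m$samples)
  per_sample_nc[is.na(per_sample_nc)] <- 0L
  gene_tot <- tapply(cells$n_variants - cells$n_causal, cells$gene, sum)
  gene_tot <- gene_tot[m$genes]
  nonzero <- gene_tot[gene_tot > 0]
  total_nc <- sum(gene_tot)
  top_k <- if (length(nonzero)) ceiling(0.10 * length(nonzero)) else 0L
  top_share <- if (total_nc > 0)
    sum(sort(nonzero, decreasing = TRUE)[seq_len(top_k)]) / total_nc
  else NA_real_
  multi <- cells[cells$n_variants >= 2, , drop = FALSE]
  structure(list(
    per_sample_counts = per_sample,
    per_sample_noncausal = per_sample_nc,
    range = c(min(per_sample), max(per_sample)),
    mean_per_sample = mean(per_sample),
    per_gene_totals = setNames(as.integer(gene_tot), m$genes),
    top_decile_share = top_share,
    multihit = c(n_pairs = nrow(multi),
                 n_variants = sum(multi$n_variants))),
    class = "landscape_stats")
}

#' @export
print.landscape_stats <- function(x, ...) {
  cat(sprintf(
    "<landscape_stats> %d samples, %d genes; variants/sample %d-%d (mean %.2f); top-decile share %.1f%%; multi-hit pairs %d (%d variants)\n",
    length(x$per_sample_counts), length(x$per_gene_totals),
    x$range[1], x$range[2], x$mean_per_sample, 100 * x$top_decile_share,
    x$multihit["n_pairs"], x$multihit["n_variants"]))
  invisible(x)
}

#' Export a landscape as plot-ready tables
#'
#' Writes a long-form TSV (one row per non-empty cell, in gene-major
#' deterministic order) and a gene x sample class-code matrix TSV.
#' Re-exporting the same landscape yields byte-identical files.
#'
#' @param m a \code{landscape_matrix}.
#' @param long_path path for the long-form table.
#' @param matrix_path optional path for the class matrix.
#' @return invisibly, the long-form data.frame.
#' @export
export_landscape <- function(m, long_path, matrix_path = NULL) {
  cells <- m$cells
  ord <- order(match(cells$gene, m$genes), match(cells$sample, m$samples))
  long <- cells[ord, c("gene", "sample", "display_class", "n_variants",
                       "causal_present"), drop = FALSE]
  rownames(long) <- NULL
  write.table(long, long_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(matrix_path)) {
    mat <- matrix(".", length(m$genes), length(m$samples),
                  dimnames = list(m$genes, m$samples))
    mat[cbind(match(cells$gene, m$genes), match(cells$sample, m$samples))] <-
      cells$display_class
    write.table(cbind(gene = rownames(mat), as.data.frame(mat)),
                matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(long)
}
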