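# Exon-level copy-number calling from a multi-sample exon x sample
# mean-depth matrix, via successive depth normalisations:
#   step 1  divide each sample column by its median exon depth
#           (library-size correction);
#   step 2  divide each exon row by a cross-sample reference (leave-one-out
#           median by default) so neutral exons sit at copy ratio 1;
#   step 3  log2-transform with a floor for zero ratios.
# Samples whose log2 ratios are over-dispersed are excluded before calling.

#' Build the exon x sample mean-depth matrix
#'
#' @param profiles a list of \code{depth_profile} objects over one panel.
#' @param panel an \code{hc_panel}; must match the profiles' panel.
#' @return a \code{coverage_matrix}: list with \code{depth} (exon x sample
#'   matrix of mean per-base depth), \code{panel}, \code{samples}.
#' @export
build_matrix <- function(profiles, panel = profiles[[1]]$panel) {
  if (length(profiles) < 2)
    stop("copy-number calling needs at least 2 samples to form a reference")
  samples <- vapply(profiles, `[[`, character(1), "sample")
  if (anyDuplicated(samples)) stop("duplicate sample identifiers")
  depth <- vapply(profiles, function(p) {
    stopifnot(length(p$depth) == sum(panel$end - panel$start))
    f <- factor(p$base_map$roi, levels = seq_len(nrow(panel)))
    vapply(split(p$depth, f), mean, numeric(1))
  }, numeric(nrow(panel)))
  dimnames(depth) <- list(NULL, samples)
  structure(list(depth = depth, panel = panel, samples = samples),
            class = "coverage_matrix")
}

#' Normalise exon depths to copy ratios
#'
#' Applies the successive normalisation steps described above. With the
#' default leave-one-out median reference, each exon's reference for a
#' given sample is the median of the other samples' library-normalised
#' depths, so a real event in the tested sample cannot contaminate its own
#' reference in small batches. \code{all_median} uses the plain
#' cross-sample median instead.
#'
#' @param mat a \code{coverage_matrix}.
#' @param reference \code{"loo_median"} (default) or \code{"all_median"}.
#' @param log2_floor smallest ratio admitted before log2 (default 2^-8).
#' @return a \code{ratio_matrix}: list with \code{ratio}, \code{log2_ratio}
#'   (exon x sample), \code{masked} (exons with no usable reference),
#'   \code{depth}, \code{panel}, \code{samples}, \code{reference}.
#' @export
cnv_normalize <- function(mat, reference = c("loo_median", "all_median"),
                          log2_floor = 2^-8) {
  reference <- match.arg(reference)
  depth <- mat$depth
  ns <- ncol(depth)
  samp_med <- apply(depth, 2, median)
  zero <- samp_med <= 0
  if (any(zero))
    stop("sample(s) with zero median exon depth: ",
         paste(mat$samples[zero], collapse = ", "))
  r <- sweep(depth, 2, samp_med, "/")
  if (reference == "loo_median") {
    ref <- matrix(NA_real_, nrow(r), ns)
    for (s in seq_len(ns))
      ref[, s] <- apply(r[, -s, drop = FALSE], 1, median)
  } else {
    ref <- matrix(apply(r, 1, median), nrow(r), ns)
  }
  masked <- apply(ref <= 0, 1, all)
  if (any(masked))
    warning(sum(masked), " exon(s) masked: zero reference depth across samples")
  ratio <- r / ref
  ratio[ref <= 0] <- NA_real_
  ratio[masked, ] <- NA_real_
  log2_ratio <- log2(pmax(ratio, log2_floor))
  dimnames(ratio) <- dimnames(log2_ratio) <- list(NULL, mat$samples)
  structure(list(ratio = ratio, log2_ratio = log2_ratio, masked = masked,
                 depth = depth, panel = mat$panel, samples = mat$samples,
                 reference = reference),
            class = "ratio_matrix")
}

#' Per-sample copy-number quality control
#'
#' A sample's dispersion is the (unscaled) median absolute deviation of
#' its unmasked log2 ratios; samples above \code{max_mad} are excluded
#' from calling, mirroring the practice of dropping samples that do not
#' reach minimum quality criteria.
#'
#' @param ratios a \code{ratio_matrix}.
#' @param max_mad maximum admissible dispersion (default 0.15).
#' @return a data.frame (\code{sample}, \code{dispersion}, \code{passed}).
#' @export
qc_samples <- function(ratios, max_mad = 0.15) {
  disp <- apply(ratios$log2_ratio[!ratios$masked, , drop = FALSE], 2,
                function(x) mad(x, constant = 1, na.rm = TRUE))
  data.frame(sample = ratios$samples, dispersion = as.numeric(disp),
             passed = as.numeric(disp) <= max_mad,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign per-exon copy-number states
#'
#' Thresholds sit between the copy ratios expected for diploid loci (1),
#' heterozygous deletions (0.5), homozygous deletions (0) and single-copy
#' duplications (1.5), with guard bands; bounds are inclusive on the
#' event side. Only samples passing QC are called; masked exons get no
#' state. An isolated exon with zero raw depth in one sample is recorded
#' as uncallable (capture dropout) rather than a homozygous deletion
#' unless at least two consecutive exons of the gene are zero.
#'
#' Calling is seed-and-extend: the hard thresholds seed an event, and a
#' neutral exon adjacent to a seeded run joins it when its ratio passes
#' the (weaker) extension threshold for that state -- the midpoint
#' between the diploid ratio 1 and the state's expected copy ratio.
#' This keeps multi-exon events intact when one boundary exon drifts
#' just inside the hard threshold, without letting isolated noise seed
#' an event.
#'
#' @param ratios a \code{ratio_matrix}.
#' @param qc output of \code{\link{qc_samples}} (computed if \code{NULL}).
#' @param het_del_max maximum ratio for a heterozygous deletion (0.65).
#' @param hom_del_max maximum ratio for a homozygous deletion (0.25).
#' @param dup_min minimum ratio for a duplication (1.35).
#' @param het_del_ext,hom_del_ext,dup_ext extension thresholds applied to
#'   exons adjacent to an already-seeded run of the matching state.
#' @return a character matrix (exon x sample) with entries
#'   \code{"neutral"}, \code{"het_del"}, \code{"hom_del"}, \code{"dup"},
#'   \code{"uncallable"} or \code{NA} (masked exon / failed sample).
#' @export
call_exons <- function(ratios, qc = NULL, het_del_max = 0.65,
                       hom_del_max = 0.25, dup_min = 1.35,
                       het_del_ext = 0.75, hom_del_ext = 0.375,
                       dup_ext = 1.25) {
  if (is.null(qc)) qc <- qc_samples(ratios)
  stopifnot(hom_del_max < het_del_max, het_del_max < 1, dup_min > 1,
            het_del_max <= het_del_ext, het_del_ext < 1, dup_ext <= dup_min)
  ratio <- ratios$ratio
  state <- matrix(NA_character_, nrow(ratio), ncol(ratio),
                  dimnames = dimnames(ratio))
  ok <- !is.na(ratio)
  state[ok] <- "neutral"
  state[ok & ratio <= het_del_max] <- "het_del"
  state[ok & ratio <= hom_del_max] <- "hom_del"
  state[ok & ratio >= dup_min] <- "dup"
  # isolated zero-depth exon: dropout, not biology
  gene <- ratios$panel$gene
  for (s in seq_len(ncol(ratio))) {
    z <- !is.na(ratio[, s]) & ratios$depth[, s] == 0
    if (!any(z)) next
    for (g in unique(gene[z])) {
      gi <- which(gene == g)
      zz <- z[gi]
      runs <- rle(zz)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      solo <- which(runs$values & runs$lengths == 1L)
      for (k in solo) state[gi[starts[k]], s] <- "uncallable"
    }
  }
  state[, !qc$passed[match(colnames(state), qc$sample)]] <- NA_character_
  state[ratios$masked, ] <- NA_character_
  # extension pass: neutral exons bordering a seeded run join it when
  # their ratio clears the matching extension threshold
  ext_ok <- function(x, st) !is.na(x) && switch(st,
    het_del = x <= het_del_ext, hom_del = x <= hom_del_ext,
    dup = x >= dup_ext, FALSE)
  gene <- ratios$panel$gene
  for (s in seq_len(ncol(state))) {
    if (all(is.na(state[, s]))) next
    for (g in unique(gene)) {
      gi <- which(gene == g)
      gi <- gi[order(ratios$panel$start[gi])]
      if (length(gi) < 2) next
      repeat {
        changed <- FALSE
        for (j in seq_along(gi)) {
          i <- gi[j]
          if (is.na(state[i, s]) || state[i, s] != "neutral") next
          for (nb in c(j - 1L, j + 1L)) {
            if (nb < 1L || nb > length(gi)) next
            nb_state <- state[gi[nb], s]
            if (!is.na(nb_state) &&
                nb_state %in% c("het_del", "hom_del", "dup") &&
                ext_ok(ratio[i, s], nb_state)) {
              state[i, s] <- nb_state
              changed <- TRUE
              break
            }
          }
        }
        if (!changed) break
      }
    }
  }
  state
}

#' Merge per-exon states into copy-number calls
#'
#' Maximal runs of consecutive exons in one gene sharing one non-neutral
#' state are merged into events. An event spanning every exon of its gene
#' is flagged whole-gene; single-exon events carry low confidence.
#'
#' @param states exon x sample state matrix from \code{\link{call_exons}}.
#' @param ratios the \code{ratio_matrix} the states were called from.
#' @return a \code{cnv_calls} data.frame: sample, gene, chrom, start, end,
#'   exon_first, exon_last, n_exons, state, mean_ratio, whole_gene,
#'   confidence.
#' @export
merge_calls <- function(states, ratios) {
  panel <- ratios$panel
  out <- list()
  for (s in colnames(states)) {
    st <- states[, s]
    for (g in unique(panel$gene)) {
      gi <- which(panel$gene == g)
      gi <- gi[order(panel$start[gi])]
      gs <- st[gi]
      gs[is.na(gs) | gs %in% c("neutral", "uncallable")] <- "."
      runs <- rle(gs)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      ev <- which(runs$values != ".")
      for (k in ev) {
        idx <- gi[starts[k]:ends[k]]
        n <- length(idx)
        exo <- panel$exon[idx]
        out[[length(out) + 1L]] <- data.frame(
          sample = s, gene = g, chrom = panel$chrom[idx[1]],
          start = min(panel$start[idx]), end = max(panel$end[idx]),
          exon_first = min(exo), exon_last = max(exo), n_exons = n,
          state = runs$values[k],
          mean_ratio = mean(ratios$ratio[idx, s]),
          whole_gene = n == length(gi),
          confidence = if (n == 1L) "low" else "high",
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample = character(), gene = character(), chrom = character(),
               start = integer(), end = integer(), exon_first = integer(),
               exon_last = integer(), n_exons = integer(), state = character(),
               mean_ratio = numeric(), whole_gene = logical(),
               confidence = character(), stringsAsFactors = FALSE)
  res <- res[order(res$sample, res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("cnv_calls", "data.frame"))
}

#' Call copy-number events end-to-end
#'
#' Convenience wrapper: normalise, QC, call, merge.
#'
#' @param mat a \code{coverage_matrix}.
#' @param reference reference mode, see \code{\link{cnv_normalize}}.
#' @param max_mad sample QC cutoff, see \code{\link{qc_samples}}.
#' @param ... thresholds passed to \code{\link{call_exons}}.
#' @return a list with \code{calls} (\code{cnv_calls}), \code{qc},
#'   \code{ratios}.
#' @export
call_cnvs <- function(mat, reference = "loo_median", max_mad = 0.15, ...) {
  ratios <- cnv_normalize(mat, reference = reference)
  qc <- qc_samples(ratios, max_mad = max_mad)
  states <- call_exons(ratios, qc, ...)
  list(calls = merge_calls(states, ratios), qc = qc, ratios = ratios)
}

#' Write copy-number calls as TSV (and optionally BED spans)
#' @param calls a \code{cnv_calls} data.frame.
#' @param path TSV output path.
#' @param bed_path optional BED output of event spans.
#' @return \code{path}, invisibly.
#' @export
write_cnv_calls <- function(calls, path, bed_path = NULL) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- as.data.frame(calls)[, c("chrom", "start", "end")]
    bed$name <- paste(calls$sample, calls$gene, calls$state, sep = "|")
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
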