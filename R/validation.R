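# Diagnostic-accuracy statistics: set comparison of expected vs observed
# variant keys, sensitivity/specificity with exact (Clopper-Pearson)
# binomial confidence intervals, and replicate concordance.

#' Canonical key of a variant
#'
#' SNVs/indels are keyed by (sample, chrom, pos, ref, alt) after
#' normalisation, so the same change parsed from different files compares
#' equal. CNV rows are keyed by (sample, gene, span, state) when span
#' columns are present, else by gene.
#'
#' @param variants an \code{hc_variants} table (or compatible data.frame).
#' @return character vector of keys.
#' @export
variant_key <- function(variants) {
  v <- as.data.frame(variants)
  key <- paste(v$sample, v$chrom, v$pos, v$ref, v$alt, sep = ":")
  if ("consequence" %in% names(v)) {
    cnv <- which(v$consequence == "cnv")
    if (length(cnv)) {
      span <- if (all(c("exon_first", "exon_last", "state") %in% names(v)))
        paste0(v$exon_first[cnv], "-", v$exon_last[cnv], ":", v$state[cnv])
      else "cnv"
      key[cnv] <- paste(v$sample[cnv], v$gene[cnv], span, sep = ":")
    }
  }
  key
}

#' Compare observed against expected variant sets
#'
#' @param expected,observed character vectors of variant keys (duplicates
#'   ignored).
#' @return a \code{detection_comparison}: list of sets \code{tp}
#'   (expected and observed), \code{fn} (expected only), \code{fp}
#'   (observed only).
#' @export
compare_detections <- function(expected, observed) {
  expected <- unique(as.character(expected))
  observed <- unique(as.character(observed))
  structure(list(expected = expected, observed = observed,
                 tp = intersect(expected, observed),
                 fn = setdiff(expected, observed),
                 fp = setdiff(observed, expected)),
            class = "detection_comparison")
}

#' @export
print.detection_comparison <- function(x, ...) {
  cat(sprintf("<detection_comparison> expected %d, observed %d: TP %d, FN %d, FP %d\n",
              length(x$expected), length(x$observed),
              length(x$tp), length(x$fn), length(x$fp)))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided interval from Beta-distribution quantiles:
#' lower = qbeta(alpha/2, x, n - x + 1) (0 when x = 0),
#' upper = qbeta(1 - alpha/2, x + 1, n - x) (1 when x = n).
#'
#' @param x number of successes.
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return a \code{binomial_ci}: list with \code{x}, \code{n},
#'   \code{estimate}, \code{lower}, \code{upper}, \code{level},
#'   \code{method}.
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  if (n < 1) stop("clopper_pearson requires n >= 1")
  if (x < 0 || x > n) stop("x must satisfy 0 <= x <= n")
  alpha <- 1 - level
  lower <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  structure(list(x = x, n = n, estimate = x / n, lower = lower,
                 upper = upper, level = level,
                 method = "Clopper-Pearson exact"),
            class = "binomial_ci")
}

#' @export
print.binomial_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%.1f-%.1f%%), %g%% CI, %s\n",
              x$x, x$n, 100 * x$estimate, 100 * x$lower, 100 * x$upper,
              100 * x$level, x$method))
  invisible(x)
}

#' Analytical sensitivity with exact CI
#' @param comparison a \code{detection_comparison} with >= 1 expected key.
#' @param level confidence level.
#' @return list with \code{fraction} and \code{ci} (a \code{binomial_ci}).
#' @export
sensitivity <- function(comparison, level = 0.95) {
  n <- length(comparison$expected)
  if (n < 1) stop("sensitivity undefined: no expected variants")
  ci <- clopper_pearson(length(comparison$tp), n, level)
  list(fraction = ci$estimate, ci = ci)
}

#' Analytical specificity with exact CI
#' @param comparison a \code{detection_comparison}.
#' @param n_negatives number of true-negative assay opportunities (>= 1).
#' @param level confidence level.
#' @return list with \code{fraction} and \code{ci}.
#' @export
specificity <- function(comparison, n_negatives, level = 0.95) {
  if (n_negatives < 1) stop("specificity undefined: n_negatives < 1")
  fp <- length(comparison$fp)
  if (fp > n_negatives) stop("more false positives than negatives")
  ci <- clopper_pearson(n_negatives - fp, n_negatives, level)
  list(fraction = ci$estimate, ci = ci)
}

#' Replicate concordance (repeatability / reproducibility)
#'
#' Concordance between two variant-call runs is the number of common
#' variants divided by the total number identified, with total read as
#' the union of the two runs' sets; the exact CI treats common/total as a
#' binomial proportion.
#'
#' @param runA,runB character vectors of variant keys; not both empty.
#' @param kind \code{"repeatability"} (within-run) or
#'   \code{"reproducibility"} (between-run) label.
#' @param level confidence level.
#' @return a \code{precision_result}: list with \code{kind},
#'   \code{concordance}, \code{ci}, \code{n_common}, \code{n_total}.
#' @export
concordance <- function(runA, runB,
                        kind = c("repeatability", "reproducibility"),
                        level = 0.95) {
  kind <- match.arg(kind)
  a <- unique(as.character(runA)); b <- unique(as.character(runB))
  n_common <- length(intersect(a, b))
  n_total <- length(union(a, b))
  if (n_total == 0) stop("concordance undefined: both runs empty")
  ci <- clopper_pearson(n_common, n_total, level)
  structure(list(kind = kind, concordance = n_common / n_total, ci = ci,
                 n_common = n_common, n_total = n_total),
            class = "precision_result")
}

#' @export
print.precision_result <- function(x, ...) {
  cat(sprintf("<%s> %d/%d = %.1f%% (%.1f-%.1f%%)\n", x$kind, x$n_common,
              x$n_total, 100 * x$concordance, 100 * x$ci$lower,
              100 * x$ci$upper))
  invisible(x)
}

#' Format a CI the way diagnostic reports print it
#' @param ci a \code{binomial_ci}.
#' @return string like "90.4\% (84.2-94.8\%)".
#' @export
format_ci <- function(ci) {
  sprintf("%.1f%% (%.1f-%.1f%%)", 100 * ci$estimate, 100 * ci$lower,
          100 * ci$upper)
}
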