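# Genome-wide imprinted-gene-count extrapolation.
#
# Informative SNPs cover only a fraction of expressed genes (the two
# stocks share much of their segregating variation), so the detected
# autosomal imprinted count undercounts the genome. The point estimate
# scales the detected count by the inverse coverage fraction.

#' Fraction of expressed genes covered by informative SNPs
#'
#' @param covered_genes Character vector of gene ids with at least one
#'   informative SNP.
#' @param expressed_genes Character vector of expressed gene ids
#'   (nonempty).
#' @return `|covered intersect expressed| / |expressed|`.
#' @export
coverage_fraction <- function(covered_genes, expressed_genes) {
  expressed <- unique(expressed_genes)
  if (length(expressed) == 0) {
    stop("`expressed_genes` must be nonempty", call. = FALSE)
  }
  length(intersect(unique(covered_genes), expressed)) / length(expressed)
}

#' Extrapolate the genome-wide imprinted-gene count
#'
#' Point estimate `n_detected / coverage`. The interval treats the
#' detected count as a binomial draw from the covered gene set
#' (Clopper-Pearson on `n_detected / n_covered`, scaled to the full
#' expressed set) when `n_covered` is supplied; otherwise an exact
#' Poisson interval on the count, scaled by `1 / coverage`.
#'
#' @param n_detected Autosomal MEG+PEG calls (XCI candidates and
#'   not-detectable genes excluded).
#' @param coverage Coverage fraction in (0, 1].
#' @param n_covered Optional size of the covered gene set.
#' @param conf Confidence level for the interval.
#' @return A `genome_estimate` list: n_detected, coverage_fraction,
#'   extrapolated_total, interval (lower, upper).
#' @export
extrapolate_total <- function(n_detected, coverage, n_covered = NULL,
                              conf = 0.95) {
  n_detected <- assert_count(n_detected, "n_detected")
  assert_fraction(coverage, "coverage", open_lo = TRUE)
  point <- n_detected / coverage
  interval <- if (!is.null(n_covered)) {
    n_covered <- assert_count(n_covered, "n_covered", min = 1L)
    ci <- binom.test(n_detected, n_covered, conf.level = conf)$conf.int
    ci * n_covered / coverage
  } else {
    alpha <- 1 - conf
    lower <- if (n_detected == 0) 0 else qgamma(alpha / 2, n_detected)
    upper <- qgamma(1 - alpha / 2, n_detected + 1)
    c(lower, upper) / coverage
  }
  structure(list(n_detected = n_detected,
                 coverage_fraction = coverage,
                 extrapolated_total = point,
                 interval = c(lower = interval[1], upper = interval[2]),
                 conf = conf),
            class = "genome_estimate")
}

#' @export
print.genome_estimate <- function(x, ...) {
  cat(sprintf(
    "Genome-wide imprinted-gene estimate\n  detected: %d\n  coverage: %.1f%%\n  extrapolated total: %.1f (%.0f%% interval %.1f-%.1f)\n",
    x$n_detected, 100 * x$coverage_fraction, x$extrapolated_total,
    100 * x$conf, x$interval[1], x$interval[2]))
  invisible(x)
}
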