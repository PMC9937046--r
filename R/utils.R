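# Shared helpers: cross-direction labels and coordinate conversions.
# Coordinate conventions used throughout the package:
#   SNP positions are 1-based (VCF convention); BED repeat intervals are
#   0-based half-open. All conversions live here.

#' Cross-direction label from parental stocks
#'
#' Directions are written `"<dam>x<sire>"`, e.g. `"LL1xLL2"` for an LL1 dam
#' mated to an LL2 sire. Direction 1 of the design is `LL1xLL2`, direction 2
#' is `LL2xLL1`.
#'
#' @param dam_stock,sire_stock Character vectors of stock labels.
#' @return Character vector of direction labels.
#' @export
cross_direction <- function(dam_stock, sire_stock) {
  paste0(dam_stock, "x", sire_stock)
}

DIR1 <- "LL1xLL2"
DIR2 <- "LL2xLL1"
STOCKS <- c("LL1", "LL2")

# 0-based half-open BED interval -> 1-based closed IRanges
bed_to_iranges <- function(start0, end0) {
  IRanges::IRanges(start = start0 + 1L, end = end0)
}

snp_granges <- function(snps) {
  GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$pos, width = 1L)
  )
}

assert_fraction <- function(x, name, lo = 0, hi = 1,
                            open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok) {
    stop(sprintf("`%s` must be a finite number in %s%s, %s%s",
                 name, if (open_lo) "(" else "[", lo, hi,
                 if (open_hi) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= min && x == as.integer(x)
  if (!ok) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
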