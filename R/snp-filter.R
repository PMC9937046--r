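# Informative-SNP discovery and filtering.
#
# A SNP is *informative* when the two parental stocks are fixed for
# opposite alleles, so that in every F1 the parental origin of each read
# is unambiguous: in the LL1(dam) x LL2(sire) direction the LL1 allele is
# maternal, in the reciprocal direction it is paternal.

#' Retain candidate SNPs by pooled read depth
#'
#' Pools ref+alt depth across all samples and keeps SNPs at or above the
#' discovery cutoff (default 40x, matching SNP discovery from a combined
#' alignment of all transcriptomes).
#'
#' @param counts Long counts tibble.
#' @param min_pooled_depth Minimum total depth pooled over all samples.
#' @return Filtered counts tibble (all samples' rows for retained SNPs).
#' @export
discover_candidate_snps <- function(counts, min_pooled_depth = 40) {
  keep <- counts |>
    dplyr::summarise(
      pooled = sum(.data$ref_count + .data$alt_count),
      .by = c("chrom", "pos")) |>
    dplyr::filter(.data$pooled >= min_pooled_depth)
  dplyr::semi_join(counts, keep, by = c("chrom", "pos"))
}

#' Call per-stock genotypes from parental allele counts
#'
#' Counts are pooled over each stock's parental samples. A stock is called
#' homozygous when the minor-allele fraction is at most `hom_max_minor_fraction`
#' (sequencing-error tolerance), heterozygous when it is at least
#' `het_min_minor_fraction`, and `unknown` otherwise or when pooled depth
#' is below `min_depth`.
#'
#' @param counts Long counts tibble.
#' @param meta Sample metadata; must contain at least one parental sample
#'   per stock.
#' @param min_depth Minimum pooled parental depth per stock.
#' @param het_min_minor_fraction Minimum minor-allele fraction for a het
#'   call.
#' @param hom_max_minor_fraction Maximum minor-allele fraction tolerated
#'   in a homozygote.
#' @return Tibble with one row per SNP: chrom, pos, ref, alt, per-stock
#'   genotype (`ref_hom`, `alt_hom`, `het`, `unknown`), pooled ref/alt
#'   counts and depths.
#' @export
genotype_stocks <- function(counts, meta, min_depth = 8,
                            het_min_minor_fraction = 0.20,
                            hom_max_minor_fraction = 0.05) {
  parental <- dplyr::filter(meta, .data$role == "parental")
  if (!all(STOCKS %in% parental$stock)) {
    stop("need at least one parental sample per stock (LL1 and LL2)",
         call. = FALSE)
  }
  pooled <- counts |>
    dplyr::inner_join(dplyr::select(parental, "sample_id", "stock"),
                      by = "sample_id") |>
    dplyr::summarise(ref_n = sum(.data$ref_count),
                     alt_n = sum(.data$alt_count),
                     .by = c("chrom", "pos", "ref", "alt", "stock"))
  call_one <- function(ref_n, alt_n) {
    depth <- ref_n + alt_n
    minor <- ifelse(depth > 0, pmin(ref_n, alt_n) / depth, NA_real_)
    dplyr::case_when(
      depth < min_depth ~ "unknown",
      minor <= hom_max_minor_fraction & ref_n >= alt_n ~ "ref_hom",
      minor <= hom_max_minor_fraction ~ "alt_hom",
      minor >= het_min_minor_fraction ~ "het",
      TRUE ~ "unknown"
    )
  }
  pooled |>
    dplyr::mutate(genotype = call_one(.data$ref_n, .data$alt_n),
                  depth = .data$ref_n + .data$alt_n) |>
    tidyr::pivot_wider(id_cols = c("chrom", "pos", "ref", "alt"),
                       names_from = "stock",
                       values_from = c("genotype", "ref_n", "alt_n", "depth"),
                       names_glue = "{tolower(stock)}_{.value}") |>
    dplyr::mutate(dplyr::across(dplyr::ends_with("_genotype"),
                                ~ dplyr::coalesce(.x, "unknown")),
                  dplyr::across(c(dplyr::ends_with("_ref_n"),
                                  dplyr::ends_with("_alt_n"),
                                  dplyr::ends_with("_depth")),
                                ~ dplyr::coalesce(.x, 0L)))
}

#' Classify SNP informativeness with parent-of-origin allele assignment
#'
#' A SNP is informative for a tissue when (i) the two stocks are opposite
#' homozygotes, (ii) each stock's own allele is supported by at least
#' `min_depth` pooled parental reads, and (iii) at least `min_f1_covered`
#' of that tissue's F1 samples reach `min_depth` total depth. The
#' parent-of-origin map follows from the cross direction: the LL1 allele
#' is maternal when the dam is LL1 and paternal when the sire is LL1.
#'
#' An optional known-genotype override (mimicking Sanger confirmation of
#' RNA-seq genotype calls) can correct stock genotypes or mark individual
#' F1 samples as homozygous; a SNP with any F1 sample confirmed
#' homozygous is uninformative (the apparent heterozygosity was a
#' miscalled variant).
#'
#' @param genotypes Output of [genotype_stocks()].
#' @param counts Long counts tibble.
#' @param meta Sample metadata.
#' @param min_f1_covered Minimum F1 samples (per tissue) at `min_depth`.
#' @param min_depth Per-sample depth floor.
#' @param genotype_override Optional tibble (chrom, pos, unit, genotype)
#'   where `unit` is `"LL1"`/`"LL2"` (stock-level correction) or an F1
#'   sample_id; genotype is `ref_hom`, `alt_hom` or `het`.
#' @return Tibble with one row per SNP x tissue: informative flag, reason
#'   when not, `ll1_allele` ("ref"/"alt"), the maternal allele in each
#'   direction, and `f1_samples_covered`.
#' @export
assess_informativeness <- function(genotypes, counts, meta,
                                   min_f1_covered = 3, min_depth = 8,
                                   genotype_override = NULL) {
  gt <- genotypes
  f1_hom_excluded <- NULL
  if (!is.null(genotype_override)) {
    ov <- tibble::as_tibble(genotype_override)
    stopifnot(all(c("chrom", "pos", "unit", "genotype") %in% names(ov)))
    for (stk in STOCKS) {
      col <- paste0(tolower(stk), "_genotype")
      so <- dplyr::filter(ov, .data$unit == stk)
      if (nrow(so) > 0) {
        idx <- match(paste(gt$chrom, gt$pos),
                     paste(so$chrom, so$pos))
        hit <- !is.na(idx)
        gt[[col]][hit] <- so$genotype[idx[hit]]
      }
    }
    f1_hom_excluded <- ov |>
      dplyr::filter(!.data$unit %in% STOCKS,
                    .data$genotype %in% c("ref_hom", "alt_hom")) |>
      dplyr::distinct(.data$chrom, .data$pos)
  }

  opposite <- (gt$ll1_genotype == "ref_hom" & gt$ll2_genotype == "alt_hom") |
    (gt$ll1_genotype == "alt_hom" & gt$ll2_genotype == "ref_hom")
  ll1_allele <- ifelse(gt$ll1_genotype == "ref_hom", "ref",
                       ifelse(gt$ll1_genotype == "alt_hom", "alt",
                              NA_character_))
  # each stock must show its own allele at >= min_depth parental reads
  own_ok <- ifelse(is.na(ll1_allele), FALSE, ifelse(
    ll1_allele == "ref",
    gt$ll1_ref_n >= min_depth & gt$ll2_alt_n >= min_depth,
    gt$ll1_alt_n >= min_depth & gt$ll2_ref_n >= min_depth))

  f1 <- dplyr::filter(meta, .data$role == "f1")
  f1_cov <- counts |>
    dplyr::inner_join(dplyr::select(f1, "sample_id", "tissue"),
                      by = "sample_id") |>
    dplyr::summarise(
      f1_samples_covered =
        sum(.data$ref_count + .data$alt_count >= min_depth),
      .by = c("chrom", "pos", "tissue"))

  base <- tibble::tibble(
    chrom = gt$chrom, pos = gt$pos, ref = gt$ref, alt = gt$alt,
    opposite_hom = opposite & own_ok,
    ll1_allele = ll1_allele,
    ll1_genotype = gt$ll1_genotype, ll2_genotype = gt$ll2_genotype
  )
  out <- tidyr::crossing(base, tissue = sort(unique(f1$tissue))) |>
    dplyr::left_join(f1_cov, by = c("chrom", "pos", "tissue")) |>
    dplyr::mutate(
      f1_samples_covered = dplyr::coalesce(.data$f1_samples_covered, 0L))
  sanger_fail <- if (!is.null(f1_hom_excluded) && nrow(f1_hom_excluded) > 0) {
    paste(out$chrom, out$pos) %in%
      paste(f1_hom_excluded$chrom, f1_hom_excluded$pos)
  } else {
    rep(FALSE, nrow(out))
  }
  out |>
    dplyr::mutate(
      informative = .data$opposite_hom &
        .data$f1_samples_covered >= min_f1_covered & !sanger_fail,
      reason = dplyr::case_when(
        sanger_fail ~ "f1_homozygous_by_override",
        !.data$opposite_hom ~ "stocks_not_opposite_homozygous",
        .data$f1_samples_covered < min_f1_covered ~ "insufficient_f1_coverage",
        TRUE ~ NA_character_
      ),
      maternal_allele_LL1xLL2 = ifelse(.data$informative,
                                       .data$ll1_allele, NA_character_),
      maternal_allele_LL2xLL1 = ifelse(
        .data$informative,
        ifelse(.data$ll1_allele == "ref", "alt", "ref"), NA_character_)
    ) |>
    dplyr::select("chrom", "pos", "ref", "alt", "tissue", "informative",
                  "reason", "ll1_allele", "maternal_allele_LL1xLL2",
                  "maternal_allele_LL2xLL1", "f1_samples_covered")
}

#' Build a mask set for SNP exclusion
#'
#' @param repeats Tibble of repeat intervals (chrom, start, end; 0-based
#'   half-open, BED convention), or `NULL`.
#' @param exons Exon tibble (gene_id, chrom, start, end; 1-based closed),
#'   or `NULL`; internal exon edges define exon-intron junctions.
#' @param boundary_distance SNPs within this many bp of a junction are
#'   masked.
#' @return A `mask_set` list.
#' @export
mask_set <- function(repeats = NULL, exons = NULL, boundary_distance = 5) {
  stopifnot(boundary_distance >= 0)
  structure(list(repeats = repeats, exons = exons,
                 boundary_distance = boundary_distance),
            class = "mask_set")
}

# exon-intron junction positions (1-based) per chrom: internal edges of
# multi-exon genes; transcript ends are not junctions
exon_junctions <- function(exons) {
  exons |>
    dplyr::arrange(.data$gene_id, .data$start) |>
    dplyr::group_by(.data$gene_id, .data$chrom) |>
    dplyr::reframe(junction = {
      n <- dplyr::n()
      if (n < 2) integer(0) else c(.data$end[-n], .data$start[-1])
    }) |>
    dplyr::distinct(.data$chrom, .data$junction)
}

#' Remove SNPs in repeats or near exon-intron boundaries
#'
#' @param snps Tibble with chrom and pos columns (any SNP-keyed table).
#' @param masks A [mask_set()].
#' @return `snps` with masked positions removed.
#' @export
apply_masks <- function(snps, masks) {
  stopifnot(inherits(masks, "mask_set"))
  drop <- rep(FALSE, nrow(snps))
  key <- snp_granges(snps)
  if (!is.null(masks$repeats) && nrow(masks$repeats) > 0) {
    rep_gr <- GenomicRanges::GRanges(
      seqnames = masks$repeats$chrom,
      ranges = bed_to_iranges(masks$repeats$start, masks$repeats$end))
    drop <- drop | IRanges::overlapsAny(key, rep_gr)
  }
  if (!is.null(masks$exons) && nrow(masks$exons) > 0) {
    jn <- exon_junctions(masks$exons)
    if (nrow(jn) > 0) {
      jn_gr <- GenomicRanges::GRanges(
        seqnames = jn$chrom,
        ranges = IRanges::IRanges(
          start = jn$junction - masks$boundary_distance,
          end = jn$junction + masks$boundary_distance))
      drop <- drop | IRanges::overlapsAny(key, jn_gr)
    }
  }
  snps[!drop, , drop = FALSE]
}
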