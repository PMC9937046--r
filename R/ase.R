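# Allelic-ratio quantification and gene-level aggregation.
#
# Per-SNP ratios are oriented to parental origin through the informative-
# SNP allele map, then pooled to gene level by summing raw counts within
# each cross direction (depth-weighted pooling, not a mean of per-SNP
# ratios). p1 and p2 are the LL1-allele expression fractions in the
# LL1xLL2 and LL2xLL1 directions, respectively.

#' Per-SNP, per-sample allelic ratios oriented to parental origin
#'
#' Computes, for every informative SNP and every F1 sample with at least
#' `min_depth` reads, the reference-allele fraction together with the
#' maternal-allele and LL1-allele fractions implied by the cross
#' direction. Samples below the depth floor are absent from the result
#' (not recorded as zero).
#'
#' @param counts Long counts tibble.
#' @param meta Sample metadata.
#' @param informative Output of [assess_informativeness()]; only rows
#'   with `informative == TRUE` contribute.
#' @param min_depth Per-sample depth floor.
#' @return Tibble with one row per informative SNP x F1 sample: chrom,
#'   pos, tissue, sample_id, direction, ref/alt counts, depth,
#'   ref_fraction, maternal_fraction, ll1_fraction, and the counts on the
#'   maternal and LL1 alleles used for pooling.
#' @export
snp_allelic_ratios <- function(counts, meta, informative, min_depth = 8) {
  info <- dplyr::filter(informative, .data$informative)
  f1 <- meta |>
    dplyr::filter(.data$role == "f1") |>
    dplyr::mutate(direction = cross_direction(.data$dam_stock,
                                              .data$sire_stock)) |>
    dplyr::select("sample_id", "tissue", "direction")
  counts |>
    dplyr::inner_join(f1, by = "sample_id") |>
    dplyr::inner_join(
      dplyr::select(info, "chrom", "pos", "tissue", "ll1_allele",
                    "maternal_allele_LL1xLL2", "maternal_allele_LL2xLL1"),
      by = c("chrom", "pos", "tissue")) |>
    dplyr::mutate(
      depth = .data$ref_count + .data$alt_count,
      maternal_allele = ifelse(.data$direction == DIR1,
                               .data$maternal_allele_LL1xLL2,
                               .data$maternal_allele_LL2xLL1)) |>
    dplyr::filter(.data$depth >= min_depth) |>
    dplyr::mutate(
      ref_fraction = .data$ref_count / .data$depth,
      maternal_count = ifelse(.data$maternal_allele == "ref",
                              .data$ref_count, .data$alt_count),
      ll1_count = ifelse(.data$ll1_allele == "ref",
                         .data$ref_count, .data$alt_count),
      maternal_fraction = .data$maternal_count / .data$depth,
      ll1_fraction = .data$ll1_count / .data$depth) |>
    dplyr::select("chrom", "pos", "ref", "alt", "tissue", "sample_id",
                  "direction", "ref_count", "alt_count", "depth",
                  "ref_fraction", "maternal_fraction", "ll1_fraction",
                  "maternal_count", "ll1_count", "maternal_allele",
                  "ll1_allele")
}

# assign each SNP to one gene: the covering gene model; ties broken by
# lexicographic gene_id (logged via message once)
assign_snps_to_genes <- function(snps, genes) {
  key <- dplyr::distinct(snps, .data$chrom, .data$pos)
  hits <- GenomicRanges::findOverlaps(
    snp_granges(key),
    GenomicRanges::GRanges(
      seqnames = genes$chrom,
      ranges = IRanges::IRanges(genes$start, genes$end)))
  map <- tibble::tibble(
    chrom = key$chrom[S4Vectors::queryHits(hits)],
    pos = key$pos[S4Vectors::queryHits(hits)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)])
  multi <- dplyr::count(map, .data$chrom, .data$pos) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    message(nrow(multi),
            " SNP(s) overlap multiple gene models; assigned to the ",
            "lexicographically first gene_id")
  }
  map |>
    dplyr::arrange(.data$chrom, .data$pos, .data$gene_id) |>
    dplyr::distinct(.data$chrom, .data$pos, .keep_all = TRUE)
}

#' Aggregate allelic ratios to gene x tissue summaries (p1, p2)
#'
#' Pools raw allele counts over all informative SNPs and F1 samples
#' within each cross direction, then computes the LL1-allele fractions
#' `p1` (LL1xLL2 direction) and `p2` (LL2xLL1 direction) and the
#' corresponding maternal fractions from the pooled counts. Genes without
#' informative SNPs are absent.
#'
#' @param ratios Output of [snp_allelic_ratios()].
#' @param genes Gene-model tibble (gene_id, chrom, start, end).
#' @return List with `gene_ase` (one row per gene x tissue: p1, p2,
#'   maternal_fraction_dir1/2, n_informative_snps, pooled depths) and
#'   `per_sample` (gene-level maternal fraction for each F1 sample, used
#'   for X-linked candidate screening and concordance inspection).
#' @export
aggregate_gene <- function(ratios, genes) {
  assigned <- ratios |>
    dplyr::inner_join(assign_snps_to_genes(ratios, genes),
                      by = c("chrom", "pos"))
  by_dir <- assigned |>
    dplyr::summarise(
      ll1 = sum(.data$ll1_count),
      maternal = sum(.data$maternal_count),
      total = sum(.data$depth),
      n_snps = dplyr::n_distinct(.data$chrom, .data$pos),
      .by = c("gene_id", "tissue", "direction"))
  wide <- by_dir |>
    tidyr::pivot_wider(
      id_cols = c("gene_id", "tissue"),
      names_from = "direction",
      values_from = c("ll1", "maternal", "total", "n_snps"))
  # directions can be missing entirely for a gene (all SNP coverage in one
  # direction); keep the columns present either way
  for (col in c(paste0("ll1_", c(DIR1, DIR2)),
                paste0("maternal_", c(DIR1, DIR2)),
                paste0("total_", c(DIR1, DIR2)),
                paste0("n_snps_", c(DIR1, DIR2)))) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  gene_ase <- wide |>
    dplyr::mutate(
      p1 = .data[[paste0("ll1_", DIR1)]] / .data[[paste0("total_", DIR1)]],
      p2 = .data[[paste0("ll1_", DIR2)]] / .data[[paste0("total_", DIR2)]],
      maternal_fraction_dir1 = .data[[paste0("maternal_", DIR1)]] /
        .data[[paste0("total_", DIR1)]],
      maternal_fraction_dir2 = .data[[paste0("maternal_", DIR2)]] /
        .data[[paste0("total_", DIR2)]],
      pooled_depth_dir1 = .data[[paste0("total_", DIR1)]],
      pooled_depth_dir2 = .data[[paste0("total_", DIR2)]],
      n_informative_snps = pmax(.data[[paste0("n_snps_", DIR1)]],
                                .data[[paste0("n_snps_", DIR2)]],
                                na.rm = TRUE)) |>
    dplyr::select("gene_id", "tissue", "p1", "p2",
                  "maternal_fraction_dir1", "maternal_fraction_dir2",
                  "n_informative_snps", "pooled_depth_dir1",
                  "pooled_depth_dir2") |>
    dplyr::arrange(.data$gene_id, .data$tissue)
  per_sample <- assigned |>
    dplyr::summarise(
      maternal_fraction = sum(.data$maternal_count) / sum(.data$depth),
      depth = sum(.data$depth),
      .by = c("gene_id", "tissue", "sample_id", "direction"))
  list(gene_ase = gene_ase, per_sample = per_sample)
}

#' Flag expression detectability per gene x tissue
#'
#' Joins upstream expression values (FPKM or a simulated analogue) and
#' flags genes at or above the detection threshold. Genes with no
#' expression value get an `NA` flag (still callable) with a warning.
#'
#' @param gene_ase Gene-level ASE tibble.
#' @param expression Tibble (gene_id, tissue, fpkm).
#' @param threshold Detection threshold (default FPKM >= 1).
#' @return `gene_ase` with `fpkm` and `expression_detected` columns.
#' @export
expression_gate <- function(gene_ase, expression, threshold = 1.0) {
  out <- gene_ase |>
    dplyr::left_join(dplyr::select(expression, "gene_id", "tissue", "fpkm"),
                     by = c("gene_id", "tissue")) |>
    dplyr::mutate(expression_detected = .data$fpkm >= threshold)
  n_missing <- sum(is.na(out$fpkm))
  if (n_missing > 0) {
    warning(n_missing, " gene x tissue record(s) lack an expression ",
            "value; detectability flagged unknown", call. = FALSE)
  }
  out
}
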