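# Packaged worked-example fixtures.
#
# `novel_imprinted_genes()` ships the published summary of the ten novel
# imprinted genes (expressed allele and allelic percentage per tissue) as
# a caller-ready fixture. `example_candidates()` builds, in code, a
# 22-gene reciprocal-cross allele-count dataset mirroring the candidate
# list at the validation stage: 19 genuine candidates plus three genes
# (Matn2, Prkaa2, Parp4) whose apparent flipped pattern traces to
# miscalled SNPs that genotype confirmation reveals to be homozygous in
# the F1s.

#' The ten-novel-imprinted-gene summary fixture
#'
#' @return Tibble with gene_id, chrom, n_informative_snps,
#'   expressed_parent, and expressed-allele percentages in fetal brain
#'   and placenta (`NA` where the gene was not detectable).
#' @export
novel_imprinted_genes <- function() {
  path <- system.file("extdata", "table1_novel_imprinted_genes.tsv",
                      package = "imprintase", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, na = "NA")
}

#' Convert the worked-example summary to gene-level ASE records
#'
#' Expressed-allele percentages translate to the direction-oriented LL1
#' fractions: a maternal percentage m gives `p1 = m, p2 = 1 - m` (the
#' maternal allele is the LL1 allele in the LL1xLL2 direction and the LL2
#' allele in the reciprocal), and a paternal percentage the mirror. Not
#' detectable tissues get `expression_detected = FALSE`.
#'
#' @param table Fixture tibble from [novel_imprinted_genes()].
#' @return Gene-level ASE tibble ready for [call_genes()].
#' @export
fixture_gene_ase <- function(table = novel_imprinted_genes()) {
  long <- table |>
    tidyr::pivot_longer(
      c("fetal_brain_percent", "placenta_percent"),
      names_to = "tissue", values_to = "percent") |>
    dplyr::mutate(tissue = sub("_percent$", "", .data$tissue))
  long |>
    dplyr::mutate(
      frac = .data$percent / 100,
      p1 = dplyr::case_when(
        is.na(.data$frac) ~ NA_real_,
        .data$expressed_parent == "Maternal" ~ .data$frac,
        TRUE ~ 1 - .data$frac),
      p2 = dplyr::case_when(
        is.na(.data$frac) ~ NA_real_,
        .data$expressed_parent == "Maternal" ~ 1 - .data$frac,
        TRUE ~ .data$frac),
      expression_detected = !is.na(.data$frac)) |>
    dplyr::select("gene_id", "tissue", "p1", "p2",
                  "n_informative_snps", "expression_detected")
}

example_candidate_genes <- function() {
  tibble::tribble(
    ~gene_id, ~chrom, ~expressed_parent, ~excluded_by_sanger,
    "H19",      "chr5",  "maternal", FALSE,
    "Igf2r",    "chr2",  "maternal", FALSE,
    "Ipncr1",   "chr1",  "maternal", FALSE,
    "Fam169a",  "chr3",  "maternal", FALSE,
    "Smc6l2",   "chrUn", "maternal", FALSE,
    "Smc6l4",   "chrUn", "maternal", FALSE,
    "Ipncr3",   "chrUn", "maternal", FALSE,
    "Ipncr4",   "chrUn", "maternal", FALSE,
    "Csnk1a1t", "chrUn", "maternal", FALSE,
    "Sytl5",    "chrUn", "maternal", FALSE,
    "Peg10",    "chr1",  "paternal", FALSE,
    "Pou5f3",   "chr1",  "paternal", FALSE,
    "Npdc1",    "chr1",  "paternal", FALSE,
    "Rwdd2a",   "chr2",  "paternal", FALSE,
    "Zfp68",    "chr2",  "paternal", FALSE,
    "Ipncr5",   "chr3",  "paternal", FALSE,
    "Ipncr2",   "chr6",  "paternal", FALSE,
    "Nkrfl1",   "chr6",  "paternal", FALSE,
    "Nkrfl2",   "chr6",  "paternal", FALSE,
    "Matn2",    "chr2",  "paternal", TRUE,
    "Prkaa2",   "chr4",  "maternal", TRUE,
    "Parp4",    "chr4",  "paternal", TRUE
  )
}

#' Deterministic 22-gene candidate-validation fixture
#'
#' Builds an allele-count dataset in which all 22 genes show a flipped
#' reciprocal expression pattern at two apparent stock-diagnostic SNPs,
#' together with a known-genotype (Sanger-style) override marking the F1
#' samples of Matn2, Prkaa2 and Parp4 homozygous at their SNPs — so the
#' informativeness filter with the override leaves 19 candidates.
#'
#' @param depth Per-F1-sample depth at each SNP.
#' @return List: counts, meta, genes, exons, sanger_override, and the
#'   candidate truth table.
#' @export
example_candidates <- function(depth = 50L) {
  cand <- example_candidate_genes()
  n <- nrow(cand)
  maternal_frac <- ifelse(cand$expressed_parent == "maternal",
                          ifelse(cand$chrom == "chrUn", 1.0, 0.98), 0.02)
  genes <- tibble::tibble(
    gene_id = cand$gene_id,
    chrom = cand$chrom,
    start = 10000L + (seq_len(n) - 1L) * 5000L,
    end = 10000L + (seq_len(n) - 1L) * 5000L + 999L,
    strand = "+"
  )
  exons <- dplyr::select(genes, "gene_id", "chrom", "start", "end")
  snps <- tibble::tibble(
    gene_id = rep(genes$gene_id, each = 2),
    chrom = rep(genes$chrom, each = 2),
    pos = rep(genes$start, each = 2) + c(100L, 500L),
    ref = "A", alt = "G",
    maternal_frac = rep(maternal_frac, each = 2)
  )
  ind <- sim_individuals(sim_config(seed = 0L))
  meta <- ind |>
    dplyr::mutate(
      tissue = "fetal_brain",
      sample_id = paste0(.data$individual, ".", .data$tissue),
      stock = ifelse(.data$role == "parental", .data$dam_stock,
                     NA_character_),
      dam_stock = ifelse(.data$role == "f1", .data$dam_stock, NA_character_),
      sire_stock = ifelse(.data$role == "f1", .data$sire_stock,
                          NA_character_)) |>
    dplyr::select("sample_id", "role", "stock", "dam_stock", "sire_stock",
                  "tissue")
  counts <- tidyr::crossing(snps, sample_id = meta$sample_id) |>
    dplyr::left_join(meta, by = "sample_id") |>
    dplyr::mutate(
      # LL1 carries ref everywhere in this fixture
      p_ref = dplyr::case_when(
        role == "parental" & stock == "LL1" ~ 1,
        role == "parental" ~ 0,
        dam_stock == "LL1" ~ maternal_frac,        # maternal allele = ref
        TRUE ~ 1 - maternal_frac),
      ref_count = as.integer(round(depth * .data$p_ref)),
      alt_count = as.integer(depth - .data$ref_count)) |>
    dplyr::select("chrom", "pos", "ref", "alt", "sample_id",
                  "ref_count", "alt_count")
  bad_snps <- dplyr::filter(snps, .data$gene_id %in%
                              cand$gene_id[cand$excluded_by_sanger])
  f1_samples <- meta$sample_id[meta$role == "f1"]
  sanger_override <- tidyr::crossing(
    dplyr::select(bad_snps, "chrom", "pos"),
    unit = f1_samples) |>
    dplyr::mutate(genotype = "ref_hom")
  list(counts = counts, meta = meta, genes = genes, exons = exons,
       sanger_override = sanger_override, candidates = cand)
}
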