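meta1 <- tiny_meta()

test_that("allele-count TSV round-trips through the loader", {
  sim <- simulate_cross_dataset(sim_config(n_genes = 5, seed = 2))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  sheet <- withr::local_tempfile(fileext = ".tsv")
  write_allele_counts(sim$counts, tsv)
  readr::write_tsv(sim$meta, sheet)
  loaded <- load_allele_counts(tsv, sheet)
  expect_equal(
    dplyr::arrange(loaded$counts, chrom, pos, sample_id),
    dplyr::arrange(sim$counts, chrom, pos, sample_id))
  expect_equal(loaded$meta$sample_id, sim$meta$sample_id)
})

test_that("VCF with allelic depths loads identically to the TSV dialect", {
  meta <- tiny_meta()
  samples <- meta$sample_id
  counts <- dplyr::bind_rows(
    uniform_counts(meta, "chr1", 100, 10, 5),
    uniform_counts(meta, "chr1", 250, 0, 12))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_allele_counts(counts, tsv)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(c(100, 250), function(p) {
    ad <- if (p == 100) "./.:10,5" else "./.:0,12"
    paste(c("chr1", p, ".", "A", "G", ".", "PASS", ".", "GT:AD",
            rep(ad, length(samples))), collapse = "\t")
  }, "")
  writeLines(c(header, body), vcf)
  from_tsv <- load_allele_counts(tsv, meta)$counts
  from_vcf <- load_allele_counts(vcf, meta)$counts
  cols <- c("chrom", "pos", "ref", "alt", "sample_id", "ref_count",
            "alt_count")
  expect_equal(
    dplyr::arrange(from_vcf[cols], pos, sample_id),
    dplyr::arrange(from_tsv[cols], pos, sample_id))
})

test_that("duplicated positions are rejected by name", {
  meta <- tiny_meta()
  counts <- dplyr::bind_rows(
    uniform_counts(meta, "chr2", 500, 4, 4),
    uniform_counts(meta, "chr2", 500, 3, 3) |>
      dplyr::mutate(ref = "C", alt = "T"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(
    tibble::tibble(chrom = c("chr2", "chr2"), pos = c(500L, 500L),
                   ref = c("A", "C"), alt = c("G", "T"),
                   `s1.ref` = c(1L, 1L), `s1.alt` = c(1L, 1L)), tsv)
  sheet <- tibble::tibble(sample_id = "s1", role = "f1",
                          tissue = "fetal_brain")
  expect_error(load_allele_counts(tsv, sheet), "chr2:500")
})

test_that("pooled-depth discovery keeps 40x and drops 39x", {
  meta <- tiny_meta()
  counts <- dplyr::bind_rows(
    uniform_counts(meta, "chr1", 100, 3, 2),   # pooled 40
    uniform_counts(meta, "chr1", 200, 3, 2) |>
      dplyr::mutate(alt_count = ifelse(sample_id == sample_id[1],
                                       1L, alt_count)))  # pooled 39
  kept <- discover_candidate_snps(counts, min_pooled_depth = 40)
  expect_equal(unique(kept$pos), 100L)
  expect_equal(nrow(discover_candidate_snps(counts[0, ], 40)), 0)
})

test_that("stock genotyping follows depth and minor-fraction rules", {
  meta <- tiny_meta()
  counts <- dplyr::bind_rows(
    # opposite homozygotes
    snp_counts("chr1", 100, setNames(
      list(c(10L, 0L), c(10L, 0L), c(0L, 9L), c(0L, 9L),
           c(5L, 5L), c(5L, 5L), c(5L, 5L), c(5L, 5L)), meta$sample_id)),
    # LL1 heterozygous
    snp_counts("chr1", 200, setNames(
      list(c(10L, 9L), c(9L, 10L), c(0L, 20L), c(0L, 20L),
           c(5L, 5L), c(5L, 5L), c(5L, 5L), c(5L, 5L)), meta$sample_id)),
    # LL1 under-covered (pooled depth 5)
    snp_counts("chr1", 300, setNames(
      list(c(3L, 0L), c(2L, 0L), c(0L, 20L), c(0L, 20L),
           c(5L, 5L), c(5L, 5L), c(5L, 5L), c(5L, 5L)), meta$sample_id)))
  gt <- dplyr::arrange(genotype_stocks(counts, meta), pos)
  expect_equal(gt$ll1_genotype, c("ref_hom", "het", "unknown"))
  expect_equal(gt$ll2_genotype, c("alt_hom", "alt_hom", "alt_hom"))
  expect_error(genotype_stocks(counts, dplyr::filter(meta, role == "f1")),
               "parental")
})

test_that("informativeness requires opposite homozygotes and F1 coverage", {
  meta <- tiny_meta()
  mk <- function(pos, parental, f1) {
    snp_counts("chr1", pos, setNames(c(parental, f1), meta$sample_id))
  }
  counts <- dplyr::bind_rows(
    # informative: opposite hom, all 4 F1s covered
    mk(100, list(c(20L, 0L), c(20L, 0L), c(0L, 18L), c(0L, 18L)),
       list(c(8L, 2L), c(9L, 1L), c(2L, 8L), c(1L, 9L))),
    # both stocks het -> uninformative
    mk(200, list(c(10L, 10L), c(10L, 10L), c(9L, 11L), c(11L, 9L)),
       list(c(8L, 2L), c(9L, 1L), c(2L, 8L), c(1L, 9L))),
    # opposite hom but only 2 of 4 F1s at >= 8x
    mk(300, list(c(20L, 0L), c(20L, 0L), c(0L, 18L), c(0L, 18L)),
       list(c(8L, 2L), c(9L, 1L), c(2L, 3L), c(1L, 2L))))
  gt <- genotype_stocks(counts, meta)
  inf <- dplyr::arrange(assess_informativeness(gt, counts, meta), pos)
  expect_equal(inf$informative, c(TRUE, FALSE, FALSE))
  expect_equal(inf$reason[2], "stocks_not_opposite_homozygous")
  expect_equal(inf$reason[3], "insufficient_f1_coverage")
  # LL1 is ref-homozygous, so in LL1xLL2 the ref allele is maternal
  expect_equal(inf$maternal_allele_LL1xLL2[1], "ref")
  expect_equal(inf$maternal_allele_LL2xLL1[1], "alt")
})

test_that("origin map swaps exactly when the directions swap", {
  meta <- tiny_meta()
  counts <- snp_counts("chr1", 100, setNames(
    list(c(20L, 0L), c(20L, 0L), c(0L, 18L), c(0L, 18L),
         c(8L, 2L), c(9L, 1L), c(2L, 8L), c(1L, 9L)), meta$sample_id))
  inf <- assess_informativeness(genotype_stocks(counts, meta), counts, meta)
  # the two directions always carry complementary maternal alleles
  expect_true(all(inf$maternal_allele_LL1xLL2 !=
                    inf$maternal_allele_LL2xLL1))
  # relabeling every F1 to the opposite direction complements each
  # sample's maternal fraction exactly
  swapped_meta <- meta |>
    dplyr::mutate(dam_stock = meta$sire_stock, sire_stock = meta$dam_stock)
  r <- snp_allelic_ratios(counts, meta, inf)
  r_sw <- snp_allelic_ratios(counts, swapped_meta, inf)
  merged <- dplyr::inner_join(r, r_sw, by = c("chrom", "pos", "sample_id"),
                              suffix = c("", "_sw"))
  expect_equal(nrow(merged), nrow(r))
  expect_equal(merged$maternal_fraction_sw, 1 - merged$maternal_fraction)
  expect_true(all(merged$direction != merged$direction_sw))
})

test_that("informativeness is monotone in depth and coverage thresholds", {
  sim <- simulate_cross_dataset(sim_config(n_genes = 40, seed = 17,
                                           stock_divergence = 0.3))
  gt <- genotype_stocks(sim$counts, sim$meta)
  base <- assess_informativeness(gt, sim$counts, sim$meta,
                                 min_f1_covered = 3, min_depth = 8)
  for (args in list(list(min_f1_covered = 4, min_depth = 8),
                    list(min_f1_covered = 3, min_depth = 20))) {
    gt2 <- genotype_stocks(sim$counts, sim$meta, min_depth = args$min_depth)
    stricter <- assess_informativeness(
      gt2, sim$counts, sim$meta,
      min_f1_covered = args$min_f1_covered, min_depth = args$min_depth)
    expect_true(all(!stricter$informative | base$informative))
  }
})

test_that("informativeness agrees with the brute-force oracle on random SNPs", {
  set.seed(42)
  meta <- tiny_meta()
  n <- 200
  counts <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    per <- lapply(seq_len(8), function(j) {
      d <- rpois(1, 14)
      r <- rbinom(1, d, sample(c(0.02, 0.5, 0.98, 0.9, 0.1), 1))
      c(as.integer(r), as.integer(d - r))
    })
    snp_counts("chr1", i * 10L, setNames(per, meta$sample_id))
  }))
  fast <- assess_informativeness(genotype_stocks(counts, meta), counts,
                                 meta)
  slow <- naive_informative(counts, meta)
  merged <- dplyr::inner_join(fast, slow,
                              by = c("chrom", "pos", "tissue"),
                              suffix = c("_fast", "_slow"))
  expect_equal(nrow(merged), n)
  expect_equal(merged$informative_fast, merged$informative_slow)
})

test_that("no truly shared-heterozygous site in a biallelic gene is informative", {
  # At imprinted genes a heterozygous parent can masquerade as homozygous
  # in RNA counts (one allele silenced), so the guarantee holds where RNA
  # reflects the genotype: biallelically expressed genes.
  sim <- simulate_cross_dataset(sim_config(
    n_genes = 80, seed = 23, stock_divergence = 0.2,
    shared_polymorphism_fraction = 0.6))
  gt <- genotype_stocks(sim$counts, sim$meta)
  inf <- assess_informativeness(gt, sim$counts, sim$meta) |>
    dplyr::filter(informative) |>
    dplyr::inner_join(sim$sites, by = c("chrom", "pos"))
  shared_het <- inf$ll1_realized == "seg" & inf$ll2_realized == "seg"
  expect_false(any(shared_het & inf$true_class == "biallelic"))
  # and informative sites in biallelic genes are realized opposite-fixed
  bi <- dplyr::filter(inf, true_class == "biallelic")
  expect_true(all(
    (bi$ll1_realized == "ref_hom" & bi$ll2_realized == "alt_hom") |
      (bi$ll1_realized == "alt_hom" & bi$ll2_realized == "ref_hom")))
})

test_that("known-genotype override removes SNPs with homozygous F1s", {
  fx <- example_candidates()
  gt <- genotype_stocks(fx$counts, fx$meta)
  no_override <- assess_informativeness(gt, fx$counts, fx$meta)
  with_override <- assess_informativeness(
    gt, fx$counts, fx$meta, genotype_override = fx$sanger_override)
  n_genes_inf <- function(inf) {
    inf |>
      dplyr::filter(informative) |>
      dplyr::inner_join(dplyr::distinct(fx$counts, chrom, pos),
                        by = c("chrom", "pos")) |>
      dplyr::inner_join(
        tibble::tibble(chrom = fx$genes$chrom, gene_id = fx$genes$gene_id,
                       start = fx$genes$start, end = fx$genes$end),
        by = "chrom", relationship = "many-to-many") |>
      dplyr::filter(pos >= start, pos <= end) |>
      dplyr::distinct(gene_id) |>
      nrow()
  }
  expect_equal(n_genes_inf(no_override), 22)
  expect_equal(n_genes_inf(with_override), 19)
  excluded <- dplyr::filter(with_override,
                            reason == "f1_homozygous_by_override")
  expect_gt(nrow(excluded), 0)
})

test_that("masks respect BED and boundary-distance conventions", {
  snps <- tibble::tibble(chrom = "chr1",
                         pos = c(100L, 994L, 996L, 2000L))
  # repeat interval [99,100) covers 1-based position 100 only
  repeats <- tibble::tibble(chrom = "chr1", start = 99L, end = 100L)
  exons <- tibble::tibble(gene_id = "g", chrom = "chr1",
                          start = c(1L, 1200L), end = c(990L, 1500L))
  masks <- mask_set(repeats = repeats, exons = exons,
                    boundary_distance = 5)
  # junction at 990: pos 994 is 4 bp away (masked), 996 is 6 bp (kept)
  kept <- apply_masks(snps, masks)
  expect_equal(kept$pos, c(996L, 2000L))
  # empty mask set is the identity
  expect_equal(apply_masks(snps, mask_set()), snps)
})
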