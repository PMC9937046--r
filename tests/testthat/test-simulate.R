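test_that("configuration validation rejects out-of-range parameters", {
  expect_error(sim_config(class_proportions = c(meg = 0.5)), "sum to 1")
  expect_error(sim_config(imprint_strength = 0.5), "imprint_strength")
  expect_error(sim_config(stock_divergence = 0.7,
                          shared_polymorphism_fraction = 0.5), "<= 1")
  expect_error(sim_config(depth_mean = -1), "depth_mean")
  expect_error(sim_config(class_proportions = c(bad = 1)), "named")
})

test_that("identical config and seed give identical output", {
  cfg <- sim_config(n_genes = 30, seed = 11)
  a <- simulate_cross_dataset(cfg)
  b <- simulate_cross_dataset(cfg)
  expect_identical(a, b)
  c2 <- simulate_cross_dataset(sim_config(n_genes = 30, seed = 12))
  expect_false(identical(a$counts, c2$counts))
})

test_that("ref + alt counts conserve the simulated depth and layout", {
  cfg <- sim_config(n_genes = 25, seed = 3, n_f1_per_direction = 2)
  sim <- simulate_cross_dataset(cfg)
  # 4 parental + 4 F1 fetuses x 2 tissues
  expect_equal(nrow(sim$meta), 16)
  expect_equal(sum(sim$meta$role == "f1"), 8)
  expect_true(all(sim$counts$ref_count >= 0 & sim$counts$alt_count >= 0))
  # every SNP present for every sample
  per_snp <- dplyr::count(sim$counts, chrom, pos)
  expect_true(all(per_snp$n == 16))
  # truth covers every gene exactly once
  expect_equal(sort(sim$truth$gene_id), sort(sim$genes$gene_id))
  expect_true(all(sim$truth$true_expressed_parent_fraction[
    sim$truth$true_class == "xci"] == 1.0))
  expect_true(all(sim$truth$chrom[sim$truth$true_class == "xci"] == "chrUn"))
})

test_that("pure MEG at strength 1 forces 100% maternal F1 expression", {
  cfg <- sim_config(
    n_genes = 10, snps_per_gene_mean = 2,
    class_proportions = c(meg = 1),
    imprint_strength = 1, error_rate = 0,
    stock_divergence = 1, shared_polymorphism_fraction = 0,
    depth_mean = 40, seed = 5)
  sim <- simulate_cross_dataset(cfg)
  f1 <- dplyr::inner_join(
    sim$counts,
    dplyr::filter(sim$meta, role == "f1"), by = "sample_id") |>
    dplyr::inner_join(dplyr::select(sim$sites, chrom, pos, ll1_allele),
                      by = c("chrom", "pos")) |>
    dplyr::filter(ref_count + alt_count > 0) |>
    dplyr::mutate(
      maternal_count = ifelse(
        (dam_stock == "LL1") == (ll1_allele == "ref"),
        ref_count, alt_count))
  expect_true(all(f1$maternal_count == f1$ref_count + f1$alt_count))
})

test_that("class fidelity: pooled fractions approach truth at high depth", {
  cfg <- sim_config(
    n_genes = 60, snps_per_gene_mean = 3,
    class_proportions = c(meg = 0.4, peg = 0.3, cis_eqtl = 0.3),
    imprint_strength = 0.9, cis_eqtl_bias = 0.8,
    stock_divergence = 1, shared_polymorphism_fraction = 0,
    depth_mean = 400, error_rate = 0, seed = 21)
  sim <- simulate_cross_dataset(cfg)
  f1 <- dplyr::inner_join(
    sim$counts, dplyr::filter(sim$meta, role == "f1"), by = "sample_id") |>
    dplyr::inner_join(
      dplyr::select(sim$sites, chrom, pos, gene_id, ll1_allele),
      by = c("chrom", "pos")) |>
    dplyr::mutate(
      direction = cross_direction(dam_stock, sire_stock),
      ll1_count = ifelse(ll1_allele == "ref", ref_count, alt_count),
      maternal_count = ifelse(
        (dam_stock == "LL1") == (ll1_allele == "ref"),
        ref_count, alt_count),
      depth = ref_count + alt_count)
  by_gene <- f1 |>
    dplyr::summarise(mat = sum(maternal_count) / sum(depth),
                     ll1 = sum(ll1_count) / sum(depth),
                     .by = c(gene_id, direction)) |>
    dplyr::inner_join(sim$truth, by = "gene_id")
  meg <- dplyr::filter(by_gene, true_class == "meg")
  expect_true(all(abs(meg$mat - 0.9) < 0.05))
  cis <- dplyr::filter(by_gene, true_class == "cis_eqtl")
  # same-side bias in both directions, near the configured value
  expect_true(all(abs(cis$ll1 - 0.8) < 0.05))
})

test_that("realized informative-site fraction matches the enumerated expectation", {
  cfg <- sim_config(n_genes = 250, snps_per_gene_mean = 3,
                    stock_divergence = 0.3,
                    shared_polymorphism_fraction = 0.5,
                    depth_mean = 60, seed = 31)
  sim <- simulate_cross_dataset(cfg)
  gt <- genotype_stocks(sim$counts, sim$meta)
  inf <- assess_informativeness(gt, sim$counts, sim$meta) |>
    dplyr::filter(tissue == "fetal_brain")
  p_hat <- mean(inf$informative)
  n <- nrow(inf)
  p_exp <- expected_informative_fraction(0.3, 0.5)
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(p_hat - p_exp), 3 * se)
})

test_that("bisulfite clone simulation honors forced probabilities", {
  res <- simulate_bisulfite_clones(20, 6, maternal_meth_prob = 1,
                                   paternal_meth_prob = 0, seed = 2)
  m <- as.matrix(res$clones[grep("^cpg_", names(res$clones))])
  mat <- res$clones$allele_tag == "maternal"
  expect_true(all(m[mat, ] == "M"))
  expect_true(all(m[!mat, ] == "U"))
  expect_error(simulate_bisulfite_clones(0, 6, 1, 0), "n_clones")
})

test_that("bisulfite per-allele means land inside the binomial 99% interval", {
  res <- simulate_bisulfite_clones(200, 12, maternal_meth_prob = 0.96,
                                   paternal_meth_prob = 0.18, seed = 9)
  m <- as.matrix(res$clones[grep("^cpg_", names(res$clones))])
  for (al in c("maternal", "paternal")) {
    p <- if (al == "maternal") 0.96 else 0.18
    rows <- res$clones$allele_tag == al
    n_calls <- sum(rows) * 12
    obs <- sum(m[rows, ] == "M")
    ci <- qbinom(c(0.005, 0.995), n_calls, p)
    expect_gte(obs, ci[1])
    expect_lte(obs, ci[2])
  }
})

test_that("allele tags are hidden without the amplicon SNP", {
  res <- simulate_bisulfite_clones(10, 4, 0.9, 0.1,
                                   with_allele_snp = FALSE, seed = 4)
  expect_true(all(res$clones$allele_tag == "unknown"))
  expect_equal(length(res$truth$allele), 10)
})
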