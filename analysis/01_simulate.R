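#!/usr/bin/env Rscript
# Simulate the reciprocal-cross study design with known truth labels.
#
# Emits the allele-count table, sample sheet, gene models and truth
# labels under results/sim/ for the downstream stages. The design: two
# stocks (LL2 sharing much of LL1's variation), 2 F1 fetuses per
# reciprocal direction, fetal brain + placenta, negative-binomial SNP
# depth around 50x.

library(imprintase)

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(
  n_genes = 400, snps_per_gene_mean = 3,
  class_proportions = c(biallelic = 0.90, meg = 0.03, peg = 0.03,
                        cis_eqtl = 0.02, xci = 0.02),
  imprint_strength = 0.97,
  stock_divergence = 0.08, shared_polymorphism_fraction = 0.55,
  depth_mean = 50, seed = 20230131)
sim <- simulate_cross_dataset(cfg)

write_allele_counts(sim$counts, file.path(out, "allele_counts.tsv"))
readr::write_tsv(sim$meta, file.path(out, "samples.tsv"))
write_gene_models(sim$genes, sim$exons, file.path(out, "genes.gff3"))
readr::write_tsv(sim$truth, file.path(out, "truth.tsv"))
readr::write_tsv(sim$expression, file.path(out, "expression.tsv"))
readr::write_tsv(sim$sites, file.path(out, "site_truth.tsv"))

n_sites <- nrow(sim$sites)
cat(sprintf("Simulated %d genes (%d SNP sites) across %d samples.\n",
            nrow(sim$genes), n_sites, nrow(sim$meta)))
cat(sprintf("Site categories: %s\n",
            paste(sprintf("%s=%d", names(table(sim$sites$category)),
                          table(sim$sites$category)), collapse = ", ")))
cat(sprintf("True gene classes: %s\n",
            paste(sprintf("%s=%d", names(table(sim$truth$true_class)),
                          table(sim$truth$true_class)), collapse = ", ")))
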