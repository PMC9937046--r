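#!/usr/bin/env Rscript
# Discover candidate SNPs and classify informativeness.
#
# Reads the simulated dataset from results/sim/, applies the discovery
# depth cutoff (pooled 40x), exon-boundary masking, stock genotyping and
# the informative-SNP rule (opposite homozygous stocks, alleles at >= 8
# parental reads, >= 3 of 4 F1 samples covered per tissue).

library(imprintase)
suppressPackageStartupMessages(library(dplyr))

inp <- "results/sim"
out <- "results/filter"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

loaded <- load_allele_counts(file.path(inp, "allele_counts.tsv"),
                             file.path(inp, "samples.tsv"))
models <- read_gene_models(file.path(inp, "genes.gff3"))

candidates <- discover_candidate_snps(loaded$counts, min_pooled_depth = 40)
masked <- apply_masks(candidates,
                      mask_set(exons = models$exons, boundary_distance = 5))
genotypes <- genotype_stocks(masked, loaded$meta, min_depth = 8)
informative <- assess_informativeness(genotypes, masked, loaded$meta,
                                      min_f1_covered = 3, min_depth = 8)

readr::write_tsv(genotypes, file.path(out, "stock_genotypes.tsv"))
readr::write_tsv(informative, file.path(out, "informative_snps.tsv"))
filter_log <- list(
  n_input_snps = nrow(distinct(loaded$counts, chrom, pos)),
  n_after_depth40 = nrow(distinct(candidates, chrom, pos)),
  n_after_masks = nrow(distinct(masked, chrom, pos)),
  n_informative = nrow(distinct(filter(informative, informative),
                                chrom, pos)))
jsonlite::write_json(filter_log, file.path(out, "filter_log.json"),
                     auto_unbox = TRUE)

cat(sprintf(
  "SNPs: %d input -> %d at pooled 40x -> %d after masks -> %d informative.\n",
  filter_log$n_input_snps, filter_log$n_after_depth40,
  filter_log$n_after_masks, filter_log$n_informative))
reasons <- count(filter(informative, !informative), reason)
cat("Uninformative reasons:",
    paste(sprintf("%s=%d", reasons$reason, reasons$n), collapse = ", "),
    "\n")
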