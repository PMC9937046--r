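#!/usr/bin/env Rscript
# Quantify allele-specific expression and call imprinting.
#
# Pools counts to gene-level p1/p2 per tissue, gates on expression
# (FPKM >= 1), applies the flipped-pattern caller (p1 > 0.65 & p2 < 0.35
# for MEG, mirror for PEG), flags XCI candidates on chrUn, and scores
# the calls against the simulation truth.

library(imprintase)
suppressPackageStartupMessages(library(dplyr))

out <- "results/calls"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

loaded <- load_allele_counts("results/sim/allele_counts.tsv",
                             "results/sim/samples.tsv")
models <- read_gene_models("results/sim/genes.gff3")
informative <- readr::read_tsv("results/filter/informative_snps.tsv",
                               show_col_types = FALSE)
expression <- readr::read_tsv("results/sim/expression.tsv",
                              show_col_types = FALSE)
truth <- readr::read_tsv("results/sim/truth.tsv", show_col_types = FALSE)

ratios <- snp_allelic_ratios(loaded$counts, loaded$meta, informative,
                             min_depth = 8)
agg <- aggregate_gene(ratios, models$genes)
gene_ase <- expression_gate(agg$gene_ase, expression, threshold = 1.0)
calls <- call_genes(gene_ase, caller_config())
calls <- flag_xci_candidates(calls, models$genes, caller_config(),
                             per_sample = agg$per_sample)
summary <- summarize_calls(calls)

readr::write_tsv(ratios, file.path(out, "snp_ratios.tsv"))
readr::write_tsv(gene_ase, file.path(out, "gene_ase.tsv"))
readr::write_tsv(calls, file.path(out, "calls.tsv"))
readr::write_tsv(summary$per_tissue, file.path(out, "per_tissue.tsv"))
readr::write_tsv(summary$cross_tissue, file.path(out, "cross_tissue.tsv"))

cat("Per-tissue calls:\n")
print.data.frame(as.data.frame(summary$per_tissue))

confusion <- calls |>
  inner_join(truth[, c("gene_id", "true_class")], by = "gene_id") |>
  count(true_class, status)
readr::write_tsv(confusion, file.path(out, "confusion.tsv"))
cat("\nCalls vs simulation truth (gene x tissue records):\n")
print.data.frame(as.data.frame(confusion))
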