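clone_tbl <- function(rows, tags = NULL) {
  n_cpg <- nchar(rows[1])
  m <- do.call(rbind, strsplit(rows, ""))
  m[m == "."] <- NA_character_
  out <- tibble::tibble(clone_id = paste0("c", seq_along(rows)),
                        allele_tag = tags %||% rep("unknown", length(rows)))
  out[paste0("cpg_", seq_len(n_cpg))] <-
    as.data.frame(m, stringsAsFactors = FALSE)
  out
}

test_that("sequence calling converts the hand-worked 7-mer correctly", {
  # reference ACGTCGA: CpGs at positions 2 and 5; clone ACGTTGA keeps the
  # first CpG cytosine (methylated) and converts the second
  cl <- call_clone_from_sequence("ACGTCGA", "ACGTTGA")
  expect_equal(cl$cpg_1, "M")
  expect_equal(cl$cpg_2, "U")
  # no non-CpG cytosine in this amplicon: conversion rate undefined
  expect_true(is.na(cl$conversion_rate))
  expect_false(cl$excluded)
})

test_that("failed-conversion controls are flagged and excluded", {
  region <- make_cpg_region(3)  # ACTCATCG x3, non-CpG Cs present
  unconverted <- call_clone_from_sequence(region, region)
  expect_equal(unconverted$conversion_rate, 0)
  expect_true(unconverted$excluded)
  fully <- call_clone_from_sequence(region, gsub("C", "T", region))
  expect_equal(fully$conversion_rate, 1)
  expect_false(fully$excluded)
  expect_true(all(unlist(fully[grep("^cpg_", names(fully))]) == "U"))
  expect_error(call_clone_from_sequence("ACGT", "ACG"), "lengths differ")
})

test_that("per-CpG percentages match the hand count and skip missing calls", {
  res <- cpg_percentages(clone_tbl(c("MMMU", "UUUU", "MUMU")))
  expect_equal(res$cpg_sites$percent_methylated,
               c(2 / 3, 1 / 3, 2 / 3, 0))
  expect_equal(res$region$mean_percent, mean(c(2 / 3, 1 / 3, 2 / 3, 0)))
  # missing calls never enter the denominator
  res2 <- cpg_percentages(clone_tbl(c("M.MU", "U.UU", "M.MU")))
  expect_equal(res2$cpg_sites$n_calls, c(3L, 0L, 3L, 3L))
  expect_equal(res2$cpg_sites$percent_methylated[2], NA_real_)
  expect_equal(res2$cpg_sites$percent_methylated[1], 2 / 3)
})

test_that("a 50/50 mix of full and empty clones averages exactly 0.5", {
  res <- cpg_percentages(clone_tbl(c("MMMM", "MMMM", "UUUU", "UUUU")))
  expect_equal(res$region$mean_percent, 0.5)
})

test_that("allele partition pools tagged clones and flags one-sided data", {
  clones <- clone_tbl(c("MMMM", "MMMU", "UUUU", "UUMU", "MUMU"),
                      tags = c("maternal", "maternal", "paternal",
                               "paternal", "unknown"))
  part <- partition_by_allele(clones)
  expect_equal(part$mean_methylation[part$allele == "maternal"], 7 / 8)
  expect_equal(part$mean_methylation[part$allele == "paternal"], 1 / 8)
  expect_false(any(part$one_sided))
  one <- partition_by_allele(clone_tbl(c("MMMM"), tags = "maternal"))
  expect_true(all(one$one_sided))
  expect_message(none <- partition_by_allele(clone_tbl(c("MMMM"))),
                 "allele partition unknown")
  expect_equal(nrow(none), 0)
})

test_that("allele-mean recovery from simulated clones hits the binomial window", {
  sim <- simulate_bisulfite_clones(200, 12, 0.96, 0.18, seed = 6)
  part <- partition_by_allele(sim$clones)
  for (al in c("maternal", "paternal")) {
    p <- if (al == "maternal") 0.96 else 0.18
    row <- part[part$allele == al, ]
    ci <- qbinom(c(0.005, 0.995), row$n_calls, p) / row$n_calls
    expect_gte(row$mean_methylation, ci[1])
    expect_lte(row$mean_methylation, ci[2])
  }
})

test_that("DMR classification follows the band and allele-difference rules", {
  region <- function(m) tibble::tibble(mean_percent = m)
  allele <- function(mat, pat) {
    tibble::tibble(allele = c("maternal", "paternal"),
                   mean_methylation = c(mat, pat),
                   n_calls = 100L, n_clones = 10L, one_sided = FALSE)
  }
  dmr <- classify_dmr(region(0.50), allele(0.96, 0.18))
  expect_equal(dmr$classification, "DMR")
  expect_equal(dmr$methylated_parent, "maternal")
  expect_equal(classify_dmr(region(0.02))$classification, "unmethylated")
  expect_equal(classify_dmr(region(0.9))$classification, "methylated")
  expect_equal(classify_dmr(region(0.5), allele(0.5, 0.5))$classification,
               "intermediate_unresolved")
  expect_equal(classify_dmr(region(0.5))$classification,
               "intermediate_unresolved")
  # monotone in allele difference at fixed mean: once a DMR, widening the
  # gap never un-calls it
  diffs <- seq(0, 1, by = 0.05)
  calls <- vapply(diffs, function(d) {
    classify_dmr(region(0.5),
                 allele(0.5 + d / 2, 0.5 - d / 2))$classification
  }, "")
  first_dmr <- match("DMR", calls)
  expect_false(is.na(first_dmr))
  expect_true(all(calls[first_dmr:length(calls)] == "DMR"))
})

test_that("sequence path equals matrix path at zero conversion failure", {
  sim <- simulate_bisulfite_clones(40, 8, 0.7, 0.2, seed = 13)
  region <- make_cpg_region(8)
  seqs <- render_clone_sequences(sim$clones, region)
  called <- call_clones_from_sequences(
    region, seqs, allele_tags = setNames(sim$clones$allele_tag,
                                         sim$clones$clone_id))
  expect_true(all(!called$excluded))
  expect_equal(cpg_percentages(called)$cpg_sites,
               cpg_percentages(sim$clones)$cpg_sites)
  expect_equal(partition_by_allele(called), partition_by_allele(sim$clones))
})

test_that("FASTA input reproduces the in-memory sequence path", {
  sim <- simulate_bisulfite_clones(10, 5, 0.8, 0.1, seed = 8)
  region <- make_cpg_region(5)
  seqs <- render_clone_sequences(sim$clones, region)
  ref_fa <- withr::local_tempfile(fileext = ".fasta")
  clones_fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">region", region), ref_fa)
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), clones_fa)
  from_fasta <- call_clones_from_fasta(ref_fa, clones_fa)
  in_memory <- call_clones_from_sequences(region, seqs)
  expect_equal(from_fasta, in_memory)
})

test_that("clone matrices round-trip through TSV with missing-call dots", {
  clones <- clone_tbl(c("M.MU", "UUUU"), tags = c("maternal", "paternal"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clone_matrix(clones, path)
  back <- read_clone_matrix(path)
  expect_equal(as.data.frame(back), as.data.frame(clones))
  # lollipop rendering marks missing with a dot
  txt <- lollipop_text(clones, filled = "*", open = "o")
  expect_match(txt[1], "\\* \\. \\* o")
})
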