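# Shared fixtures and independent oracles used across the suite.

# minimal sample metadata: 2 parental samples per stock + 2 F1 per
# direction, one tissue
tiny_meta <- function(tissue = "fetal_brain") {
  tibble::tibble(
    sample_id = paste0(c("LL1p1", "LL1p2", "LL2p1", "LL2p2",
                         "F1_LL1xLL2_1", "F1_LL1xLL2_2",
                         "F1_LL2xLL1_1", "F1_LL2xLL1_2"), ".", tissue),
    role = c(rep("parental", 4), rep("f1", 4)),
    stock = c("LL1", "LL1", "LL2", "LL2", rep(NA, 4)),
    dam_stock = c(rep(NA, 4), "LL1", "LL1", "LL2", "LL2"),
    sire_stock = c(rep(NA, 4), "LL2", "LL2", "LL1", "LL1"),
    tissue = tissue
  )
}

# build a long counts tibble from a per-sample (ref, alt) list for one SNP
snp_counts <- function(chrom, pos, per_sample, ref = "A", alt = "G") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    sample_id = names(per_sample),
    ref_count = unname(vapply(per_sample, `[`, 0L, 1L)),
    alt_count = unname(vapply(per_sample, `[`, 0L, 2L))
  )
}

# uniform counts across all samples of a meta sheet
uniform_counts <- function(meta, chrom, pos, ref_n, alt_n) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = "A", alt = "G",
    sample_id = meta$sample_id,
    ref_count = as.integer(ref_n), alt_count = as.integer(alt_n)
  )
}

# Independent brute-force informativeness oracle: plain loops over SNPs,
# re-deriving stock genotypes and the informative rule from first
# principles (no shared code with assess_informativeness).
naive_informative <- function(counts, meta, min_f1_covered = 3,
                              min_depth = 8, het_min = 0.20,
                              hom_max = 0.05) {
  key <- unique(counts[, c("chrom", "pos")])
  tissues <- unique(meta$tissue[meta$role == "f1"])
  out <- list()
  for (i in seq_len(nrow(key))) {
    rows <- counts[counts$chrom == key$chrom[i] & counts$pos == key$pos[i], ]
    gcall <- function(stock) {
      ids <- meta$sample_id[meta$role == "parental" &
                              !is.na(meta$stock) & meta$stock == stock]
      r <- sum(rows$ref_count[rows$sample_id %in% ids])
      a <- sum(rows$alt_count[rows$sample_id %in% ids])
      d <- r + a
      if (d < min_depth) return(list(g = "unknown", r = r, a = a))
      minor <- min(r, a) / d
      g <- if (minor <= hom_max) {
        if (r >= a) "ref_hom" else "alt_hom"
      } else if (minor >= het_min) "het" else "unknown"
      list(g = g, r = r, a = a)
    }
    g1 <- gcall("LL1")
    g2 <- gcall("LL2")
    # enumerate the 9 genotype-pair combinations: only the two
    # opposite-homozygote pairs are informative
    pair_ok <- (g1$g == "ref_hom" && g2$g == "alt_hom") ||
      (g1$g == "alt_hom" && g2$g == "ref_hom")
    own_ok <- FALSE
    if (pair_ok) {
      own_ok <- if (g1$g == "ref_hom") {
        g1$r >= min_depth && g2$a >= min_depth
      } else {
        g1$a >= min_depth && g2$r >= min_depth
      }
    }
    for (tis in tissues) {
      ids <- meta$sample_id[meta$role == "f1" & meta$tissue == tis]
      f1_rows <- rows[rows$sample_id %in% ids, ]
      covered <- sum(f1_rows$ref_count + f1_rows$alt_count >= min_depth)
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = key$chrom[i], pos = key$pos[i], tissue = tis,
        informative = pair_ok && own_ok && covered >= min_f1_covered)
    }
  }
  dplyr::bind_rows(out)
}

# closed-form expected informative-site fraction for the generator's
# site model, by enumerating parental genotype-pair probabilities: with
# 2 sampled animals (4 alleles) per stock, a site is informative iff one
# stock's 4 alleles are all one allele and the other stock's all the
# other (depth effects ignored; exact in the high-depth limit)
expected_informative_fraction <- function(stock_divergence,
                                          shared_fraction) {
  p_all <- function(freq_alt, allele) {
    p <- if (allele == "alt") freq_alt else 1 - freq_alt
    p^4
  }
  # fixed-different sites: always opposite-fixed
  p_fixed <- stock_divergence
  # shared sites (alt freq 0.5 in both stocks): both orientations
  p_shared <- shared_fraction *
    (p_all(0.5, "ref") * p_all(0.5, "alt") +
       p_all(0.5, "alt") * p_all(0.5, "ref"))
  # fixed-same sites: never opposite
  p_fixed + p_shared
}
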