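# Synthetic reciprocal-cross generator.
#
# Emulates the study design the pipeline was built for: two random-bred
# stocks (LL1, LL2; LL2 carries substantial admixture from the LL1 source
# population, so many polymorphisms segregate in both stocks), reciprocal
# F1 crosses with two fetuses per direction, and two tissues per fetus
# (fetal brain and placenta). Every simulated gene carries a truth label
# so downstream stages can be scored for parameter recovery.

#' Simulation configuration for the reciprocal-cross generator
#'
#' Defaults emulate the cross design the pipeline targets: 2 F1 fetuses per
#' reciprocal direction, fetal brain + placenta, overdispersed per-SNP
#' depth (negative binomial), a modest fraction of stock-diagnostic
#' (fixed-different) sites and a large fraction of shared segregating
#' polymorphism, reflecting random-bred stocks with partially shared
#' ancestry.
#'
#' @param n_genes Number of genes to simulate.
#' @param snps_per_gene_mean Mean exonic SNPs per gene (Poisson, floored
#'   at 1).
#' @param class_proportions Named proportions over gene classes
#'   `biallelic`, `meg`, `peg`, `cis_eqtl`, `xci`; must sum to 1.
#' @param imprint_strength Expressed-parent allele fraction for MEG/PEG
#'   genes, in (0.5, 1].
#' @param cis_eqtl_bias Biased-allele expression fraction for cis-eQTL
#'   genes, in (0.5, 1]; the bias sits on the same allele in both cross
#'   directions (no flip).
#' @param stock_divergence Probability a site is fixed for opposite
#'   alleles in the two stocks (the informative class).
#' @param shared_polymorphism_fraction Probability a site segregates in
#'   both stocks (allele frequency 0.5 in each); these sites are
#'   uninformative for parental origin.
#' @param depth_mean,depth_dispersion Negative-binomial mean and size for
#'   per-SNP, per-sample read depth.
#' @param error_rate Per-read base-call/contamination error; homozygous
#'   sites show this minor-allele fraction in expectation.
#' @param n_f1_per_direction F1 fetuses per reciprocal direction.
#' @param tissues Tissue labels; each fetus contributes one sample per
#'   tissue.
#' @param seed Integer seed; identical config + seed gives identical
#'   output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 200,
                       snps_per_gene_mean = 3,
                       class_proportions = c(biallelic = 0.80, meg = 0.05,
                                             peg = 0.05, cis_eqtl = 0.05,
                                             xci = 0.05),
                       imprint_strength = 0.97,
                       cis_eqtl_bias = 0.75,
                       stock_divergence = 0.08,
                       shared_polymorphism_fraction = 0.55,
                       depth_mean = 50,
                       depth_dispersion = 5,
                       error_rate = 0.005,
                       n_f1_per_direction = 2,
                       tissues = c("fetal_brain", "placenta"),
                       seed = 1L) {
  classes <- c("biallelic", "meg", "peg", "cis_eqtl", "xci")
  class_proportions <- unlist(class_proportions)  # accept YAML-style lists
  if (is.null(names(class_proportions)) ||
      !all(names(class_proportions) %in% classes)) {
    stop("`class_proportions` must be named with a subset of: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  props <- setNames(numeric(length(classes)), classes)
  props[names(class_proportions)] <- class_proportions
  if (any(!is.finite(props)) || any(props < 0)) {
    stop("`class_proportions` must be finite and non-negative",
         call. = FALSE)
  }
  if (abs(sum(props) - 1) > 1e-9) {
    stop("`class_proportions` must sum to 1 (tolerance 1e-9)",
         call. = FALSE)
  }
  assert_count(n_genes, "n_genes", min = 1L)
  if (!is.numeric(snps_per_gene_mean) || snps_per_gene_mean <= 0) {
    stop("`snps_per_gene_mean` must be positive", call. = FALSE)
  }
  assert_fraction(imprint_strength, "imprint_strength",
                  lo = 0.5, open_lo = TRUE)
  assert_fraction(cis_eqtl_bias, "cis_eqtl_bias", lo = 0.5, open_lo = TRUE)
  assert_fraction(stock_divergence, "stock_divergence")
  assert_fraction(shared_polymorphism_fraction,
                  "shared_polymorphism_fraction")
  if (stock_divergence + shared_polymorphism_fraction > 1 + 1e-12) {
    stop("`stock_divergence` + `shared_polymorphism_fraction` must be <= 1",
         call. = FALSE)
  }
  if (!is.numeric(depth_mean) || !is.finite(depth_mean) || depth_mean <= 0) {
    stop("`depth_mean` must be a positive finite number", call. = FALSE)
  }
  if (!is.numeric(depth_dispersion) || !is.finite(depth_dispersion) ||
      depth_dispersion <= 0) {
    stop("`depth_dispersion` must be a positive finite number",
         call. = FALSE)
  }
  assert_fraction(error_rate, "error_rate", hi = 0.5, open_hi = TRUE)
  assert_count(n_f1_per_direction, "n_f1_per_direction", min = 1L)
  stopifnot(length(tissues) >= 1, is.character(tissues))
  seed <- assert_count(seed, "seed")
  structure(list(
    n_genes = as.integer(n_genes),
    snps_per_gene_mean = snps_per_gene_mean,
    class_proportions = props,
    imprint_strength = imprint_strength,
    cis_eqtl_bias = cis_eqtl_bias,
    stock_divergence = stock_divergence,
    shared_polymorphism_fraction = shared_polymorphism_fraction,
    depth_mean = depth_mean,
    depth_dispersion = depth_dispersion,
    error_rate = error_rate,
    n_f1_per_direction = as.integer(n_f1_per_direction),
    tissues = tissues,
    seed = seed
  ), class = "sim_config")
}

# Individual layout: 2 parental-cross fetuses per stock (LL1xLL1,
# LL2xLL2) plus n_f1_per_direction fetuses per reciprocal direction.
# Each fetus yields one sample per tissue; sample_id = "<fetus>.<tissue>".
sim_individuals <- function(config) {
  n <- config$n_f1_per_direction
  tibble::tibble(
    individual = c(paste0("LL1p", seq_len(2)), paste0("LL2p", seq_len(2)),
                   paste0("F1_", DIR1, "_", seq_len(n)),
                   paste0("F1_", DIR2, "_", seq_len(n))),
    role = c(rep("parental", 4), rep("f1", 2 * n)),
    dam_stock = c("LL1", "LL1", "LL2", "LL2",
                  rep("LL1", n), rep("LL2", n)),
    sire_stock = c("LL1", "LL1", "LL2", "LL2",
                   rep("LL2", n), rep("LL1", n))
  )
}

#' Simulate a reciprocal-cross allele-count dataset with known truth
#'
#' Generates per-SNP reference/alternative read counts for all samples of
#' a two-stock reciprocal cross. Each site falls into one of three
#' genotype categories: fixed-different between the stocks (informative:
#' every F1 is heterozygous with known parental origin of each allele),
#' segregating in both stocks (shared polymorphism, uninformative), or
#' fixed identical. Expression of the two alleles in each fetus follows
#' the gene's true class: biallelic (50/50), MEG/PEG (expressed-parent
#' fraction = `imprint_strength`, flipping with cross direction),
#' cis-eQTL (fixed allelic bias that does not flip), or imprinted-XCI
#' (100% maternal; such genes are placed on the unassembled scaffold
#' label `chrUn`). Read counts are binomial draws at negative-binomial
#' depths, with a small symmetric error rate.
#'
#' @param config A [sim_config()].
#' @return A list with tibbles:
#' \describe{
#'   \item{counts}{long allele counts: chrom, pos, ref, alt, sample_id,
#'     ref_count, alt_count.}
#'   \item{meta}{sample metadata (sample_id, role, stock, dam_stock,
#'     sire_stock, tissue).}
#'   \item{genes, exons}{gene models (two exons per gene).}
#'   \item{truth}{per-gene truth labels (true_class,
#'     true_expressed_parent_fraction, chrom).}
#'   \item{sites}{per-SNP truth (category, biased/LL1 allele, realized
#'     parental-stock genotypes).}
#'   \item{expression}{per gene x tissue FPKM-like expression values.}
#' }
#' @export
simulate_cross_dataset <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be created by sim_config()", call. = FALSE)
  }
  set.seed(config$seed)
  classes <- names(config$class_proportions)

  ## genes ----------------------------------------------------------------
  gene_class <- sample(classes, config$n_genes, replace = TRUE,
                       prob = config$class_proportions)
  chrom <- ifelse(gene_class == "xci", "chrUn",
                  sample(paste0("chr", 1:8), config$n_genes, replace = TRUE))
  idx_on_chrom <- stats::ave(seq_along(chrom), chrom, FUN = seq_along)
  gene_start <- 10000L + (idx_on_chrom - 1L) * 10000L
  genes <- tibble::tibble(
    gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
    chrom = chrom,
    start = gene_start,
    end = gene_start + 4999L,
    strand = "+"
  )
  # two exons per gene, intron in the middle, so exon-boundary masking is
  # exercisable on simulated data
  exons <- tibble::tibble(
    gene_id = rep(genes$gene_id, each = 2),
    chrom = rep(genes$chrom, each = 2),
    start = as.integer(rep(genes$start, each = 2) + c(0L, 3000L)),
    end = as.integer(rep(genes$start, each = 2) + c(1999L, 4999L))
  )
  strength <- config$imprint_strength
  truth <- tibble::tibble(
    gene_id = genes$gene_id,
    true_class = gene_class,
    true_expressed_parent_fraction = dplyr::case_when(
      gene_class == "meg" ~ strength,
      gene_class == "peg" ~ strength,
      gene_class == "xci" ~ 1.0,
      TRUE ~ 0.5
    ),
    chrom = genes$chrom
  )

  ## SNP sites ------------------------------------------------------------
  n_snps_gene <- pmax(1L, rpois(config$n_genes, config$snps_per_gene_mean))
  # offsets within the gene that sit >= 10 bp inside an exon, so default
  # boundary masking does not remove simulated sites
  allowed_offsets <- c(10:1989, 3010:4989)
  snp_offsets <- lapply(n_snps_gene, function(k) {
    sort(sample(allowed_offsets, k))
  })
  sites <- tibble::tibble(
    gene_id = rep(genes$gene_id, n_snps_gene),
    chrom = rep(genes$chrom, n_snps_gene),
    pos = rep(genes$start, n_snps_gene) + unlist(snp_offsets),
    true_class = rep(gene_class, n_snps_gene)
  )
  n_sites <- nrow(sites)
  u <- runif(n_sites)
  sites$category <- ifelse(
    u < config$stock_divergence, "fixed_diff",
    ifelse(u < config$stock_divergence + config$shared_polymorphism_fraction,
           "shared_poly", "fixed_same"))
  bases <- c("A", "C", "G", "T")
  sites$ref <- sample(bases, n_sites, replace = TRUE)
  sites$alt <- unname(vapply(sites$ref,
                             function(r) sample(setdiff(bases, r), 1L), ""))
  # which named allele the LL1 stock carries at fixed-different sites;
  # also the allele that carries the cis-eQTL bias
  sites$ll1_allele <- ifelse(sites$category == "fixed_diff",
                             sample(c("ref", "alt"), n_sites, replace = TRUE),
                             "ref")

  # per-stock ALT allele frequency
  fa <- cbind(
    LL1 = ifelse(sites$category == "fixed_diff",
                 ifelse(sites$ll1_allele == "alt", 1, 0),
                 ifelse(sites$category == "shared_poly", 0.5, 0)),
    LL2 = ifelse(sites$category == "fixed_diff",
                 ifelse(sites$ll1_allele == "alt", 0, 1),
                 ifelse(sites$category == "shared_poly", 0.5, 0))
  )

  ## individuals and genotypes --------------------------------------------
  ind <- sim_individuals(config)
  n_ind <- nrow(ind)
  dam_alt <- matrix(0L, n_sites, n_ind)
  sire_alt <- matrix(0L, n_sites, n_ind)
  for (i in seq_len(n_ind)) {
    dam_alt[, i] <- rbinom(n_sites, 1L, fa[, ind$dam_stock[i]])
    sire_alt[, i] <- rbinom(n_sites, 1L, fa[, ind$sire_stock[i]])
  }
  # realized per-stock genotype over the sampled parental animals (truth
  # channel): a shared-polymorphism site can still *look* fixed-opposite
  # when the few sampled parents are, by chance, opposite homozygotes
  stock_truth <- function(stock) {
    cols <- which(ind$role == "parental" & ind$dam_stock == stock)
    dose <- rowSums(dam_alt[, cols, drop = FALSE]) +
      rowSums(sire_alt[, cols, drop = FALSE])
    n_alleles <- 2L * length(cols)
    ifelse(dose == 0L, "ref_hom",
           ifelse(dose == n_alleles, "alt_hom", "seg"))
  }
  sites$ll1_realized <- stock_truth("LL1")
  sites$ll2_realized <- stock_truth("LL2")

  ## expected ALT-read fraction per site x individual ---------------------
  # maternal-allele expressed fraction by class (parental origin = dam
  # allele; applies in every fetus, including parental-cross fetuses)
  mu_maternal <- dplyr::case_when(
    sites$true_class == "meg" ~ strength,
    sites$true_class == "peg" ~ 1 - strength,
    sites$true_class == "xci" ~ 1.0,
    TRUE ~ 0.5
  )
  biased_is_alt <- sites$ll1_allele == "alt"
  p_alt <- matrix(0, n_sites, n_ind)
  for (i in seq_len(n_ind)) {
    hom <- dam_alt[, i] == sire_alt[, i]
    p <- ifelse(sites$true_class == "cis_eqtl",
                # bias rides the named allele, never flips with direction
                ifelse(biased_is_alt, config$cis_eqtl_bias,
                       1 - config$cis_eqtl_bias),
                # parent-of-origin classes: expressed fraction of dam allele
                ifelse(dam_alt[, i] == 1L, mu_maternal, 1 - mu_maternal))
    p[hom] <- dam_alt[hom, i]
    p_alt[, i] <- p
  }
  e <- config$error_rate
  p_alt <- p_alt * (1 - 2 * e) + e

  ## read counts per tissue -----------------------------------------------
  count_blocks <- lapply(config$tissues, function(tis) {
    depth <- matrix(
      rnbinom(n_sites * n_ind, size = config$depth_dispersion,
              mu = config$depth_mean),
      n_sites, n_ind)
    altc <- matrix(rbinom(n_sites * n_ind, as.vector(depth),
                          as.vector(p_alt)), n_sites, n_ind)
    tibble::tibble(
      chrom = rep(sites$chrom, n_ind),
      pos = rep(sites$pos, n_ind),
      ref = rep(sites$ref, n_ind),
      alt = rep(sites$alt, n_ind),
      sample_id = rep(paste0(ind$individual, ".", tis), each = n_sites),
      ref_count = as.integer(as.vector(depth - altc)),
      alt_count = as.integer(as.vector(altc))
    )
  })
  counts <- dplyr::arrange(dplyr::bind_rows(count_blocks),
                           .data$chrom, .data$pos, .data$sample_id)

  meta <- tidyr::crossing(ind, tissue = config$tissues) |>
    dplyr::mutate(
      sample_id = paste0(.data$individual, ".", .data$tissue),
      stock = ifelse(.data$role == "parental", .data$dam_stock, NA_character_),
      dam_stock = ifelse(.data$role == "f1", .data$dam_stock, NA_character_),
      sire_stock = ifelse(.data$role == "f1", .data$sire_stock, NA_character_)
    ) |>
    dplyr::select("sample_id", "role", "stock", "dam_stock", "sire_stock",
                  "tissue")

  expression <- tidyr::crossing(gene_id = genes$gene_id,
                                tissue = config$tissues) |>
    dplyr::mutate(fpkm = rlnorm(dplyr::n(), meanlog = log(20), sdlog = 1.2))

  list(counts = counts, meta = meta, genes = genes, exons = exons,
       truth = truth,
       sites = dplyr::select(sites, "chrom", "pos", "ref", "alt", "gene_id",
                             "category", "ll1_allele", "true_class",
                             "ll1_realized", "ll2_realized"),
       expression = expression)
}

#' Simulate bisulfite clone methylation calls with known truth
#'
#' Each cloned molecule is tagged maternal or paternal with probability
#' 0.5 (mimicking a perfectly linked allele-tag SNP inside the amplicon);
#' each CpG is methylated with the tagged allele's probability, and
#' unmethylated calls flip to apparent methylation at the incomplete-
#' conversion error rate.
#'
#' @param n_clones Number of clones (>= 1).
#' @param n_cpgs CpG sites per clone.
#' @param maternal_meth_prob,paternal_meth_prob Per-CpG methylation
#'   probability on each parental allele.
#' @param conversion_failure_rate Probability an unmethylated cytosine
#'   escapes conversion and reads as methylated.
#' @param with_allele_snp When `FALSE`, the allele tag is hidden
#'   (`"unknown"`) as when the amplicon has no informative SNP.
#' @param seed Integer seed.
#' @return List with `clones` (tibble: clone_id, allele_tag, cpg_1..n of
#'   "M"/"U") and `truth` (hidden allele of every clone plus the
#'   generating probabilities).
#' @export
simulate_bisulfite_clones <- function(n_clones, n_cpgs,
                                      maternal_meth_prob,
                                      paternal_meth_prob,
                                      conversion_failure_rate = 0,
                                      with_allele_snp = TRUE,
                                      seed = 1L) {
  assert_count(n_clones, "n_clones", min = 1L)
  assert_count(n_cpgs, "n_cpgs", min = 1L)
  assert_fraction(maternal_meth_prob, "maternal_meth_prob")
  assert_fraction(paternal_meth_prob, "paternal_meth_prob")
  assert_fraction(conversion_failure_rate, "conversion_failure_rate")
  set.seed(assert_count(seed, "seed"))
  allele <- sample(c("maternal", "paternal"), n_clones, replace = TRUE)
  prob <- ifelse(allele == "maternal", maternal_meth_prob,
                 paternal_meth_prob)
  meth <- matrix(rbinom(n_clones * n_cpgs, 1L, rep(prob, n_cpgs)),
                 n_clones, n_cpgs)
  if (conversion_failure_rate > 0) {
    fail <- matrix(rbinom(n_clones * n_cpgs, 1L, conversion_failure_rate),
                   n_clones, n_cpgs)
    meth <- pmax(meth, fail)  # unconverted unmethylated C reads as M
  }
  calls <- matrix(ifelse(meth == 1L, "M", "U"), n_clones, n_cpgs,
                  dimnames = list(NULL, paste0("cpg_", seq_len(n_cpgs))))
  clones <- dplyr::bind_cols(
    tibble::tibble(
      clone_id = sprintf("clone%03d", seq_len(n_clones)),
      allele_tag = if (with_allele_snp) allele else "unknown"
    ),
    tibble::as_tibble(calls)
  )
  list(clones = clones,
       truth = list(allele = allele,
                    maternal_meth_prob = maternal_meth_prob,
                    paternal_meth_prob = paternal_meth_prob,
                    conversion_failure_rate = conversion_failure_rate))
}

#' Reference region with a known CpG layout
#'
#' Deterministic repeat of the 8-mer `ACTCATCG`: one CpG per unit plus two
#' non-CpG cytosines, giving conversion-efficiency signal alongside the
#' methylation-informative sites.
#'
#' @param n_cpgs Number of CpG sites (repeat units).
#' @return A single DNA string.
#' @export
make_cpg_region <- function(n_cpgs = 12) {
  assert_count(n_cpgs, "n_cpgs", min = 1L)
  strrep("ACTCATCG", n_cpgs)
}

#' Render bisulfite-converted read sequences from a clone call matrix
#'
#' Inverse of [call_clone_from_sequence()]: CpG cytosines called `M` stay
#' `C`, those called `U` become `T`; non-CpG cytosines convert to `T`
#' except a fraction retained unconverted (simulating incomplete
#' conversion at the sequence level).
#'
#' @param clones Clone tibble from [simulate_bisulfite_clones()].
#' @param region Reference region DNA string whose CpG count matches the
#'   clone matrix width.
#' @param retain_nonconverted Probability a non-CpG cytosine stays `C`.
#' @param seed Seed used when `retain_nonconverted > 0`.
#' @return Named character vector of clone sequences.
#' @export
render_clone_sequences <- function(clones, region,
                                   retain_nonconverted = 0, seed = 1L) {
  ref <- strsplit(region, "")[[1]]
  cpg_c <- which(ref == "C" & c(ref[-1], "") == "G")
  noncpg_c <- setdiff(which(ref == "C"), cpg_c)
  call_cols <- grep("^cpg_", names(clones), value = TRUE)
  if (length(call_cols) != length(cpg_c)) {
    stop("clone matrix width does not match region CpG count",
         call. = FALSE)
  }
  if (retain_nonconverted > 0) set.seed(assert_count(seed, "seed"))
  seqs <- vapply(seq_len(nrow(clones)), function(i) {
    s <- ref
    calls <- as.character(clones[i, call_cols])
    s[cpg_c] <- ifelse(calls == "M", "C", "T")
    if (retain_nonconverted > 0) {
      keep <- runif(length(noncpg_c)) < retain_nonconverted
      s[noncpg_c] <- ifelse(keep, "C", "T")
    } else {
      s[noncpg_c] <- "T"
    }
    paste(s, collapse = "")
  }, "")
  setNames(seqs, clones$clone_id)
}
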