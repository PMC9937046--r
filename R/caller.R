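# Flipped-pattern imprinting classification.
#
# A gene is called imprinted only when its allelic bias *flips* between
# the reciprocal crosses: MEG iff p1 > upper and p2 < lower (LL1 allele
# favored when LL1 is the dam, disfavored when LL1 is the sire), PEG for
# the mirror pattern. A bias on the same side of 0.5 in both directions
# is the signature of a cis-eQTL, never called imprinted.

#' Caller thresholds
#'
#' @param upper,lower Allelic-imbalance cutoffs; `lower` must equal
#'   `1 - upper`. Defaults 0.65 / 0.35.
#' @param xci_maternal_min Minimal per-sample maternal fraction for the
#'   imprinted-XCI candidate flag (0.99 tolerates single stray reads in
#'   an effectively 100%-maternal gene).
#' @param strict_inequality Imprinting requires strictly exceeding the
#'   cutoffs; boundary values fall back to biallelic/undetermined.
#' @return A `caller_config` list.
#' @export
caller_config <- function(upper = 0.65, lower = 0.35,
                          xci_maternal_min = 0.99,
                          strict_inequality = TRUE) {
  assert_fraction(upper, "upper", lo = 0.5, hi = 1,
                  open_lo = TRUE, open_hi = TRUE)
  if (abs(lower - (1 - upper)) > 1e-12) {
    stop("`lower` must equal 1 - `upper`", call. = FALSE)
  }
  assert_fraction(xci_maternal_min, "xci_maternal_min")
  structure(list(upper = upper, lower = lower,
                 xci_maternal_min = xci_maternal_min,
                 strict_inequality = isTRUE(strict_inequality)),
            class = "caller_config")
}

#' Classify gene x tissue records as MEG / PEG / biallelic / undetermined
#'
#' Requires the flipped reciprocal pattern: MEG iff `p1 > upper` and
#' `p2 < lower`; PEG iff `p1 < lower` and `p2 > upper`; biallelic iff
#' both ratios lie inside `[lower, upper]`; everything else (including
#' same-side cis-eQTL patterns, mixed boundary cases, and genes with a
#' missing direction) is undetermined. Records whose expression gate is
#' `FALSE` are `not_detectable`. An informational exact binomial test of
#' each direction's pooled counts against 0.5 is annotated when pooled
#' depths are available; it never changes a call.
#'
#' @param gene_ase Gene-level ASE tibble (needs gene_id, tissue, p1, p2;
#'   optional expression_detected, pooled depths, n_informative_snps).
#' @param cfg A [caller_config()].
#' @return Calls tibble: status, expressed_parent, per-direction
#'   expressed-parent fractions, flipped flag, and evidence summary.
#' @export
call_genes <- function(gene_ase, cfg = caller_config()) {
  stopifnot(inherits(cfg, "caller_config"))
  u <- cfg$upper
  l <- cfg$lower
  gt <- if (cfg$strict_inequality) `>` else `>=`
  lt <- if (cfg$strict_inequality) `<` else `<=`
  df <- gene_ase
  if (!"expression_detected" %in% names(df)) {
    df$expression_detected <- NA
  }
  for (col in c("n_informative_snps", "pooled_depth_dir1",
                "pooled_depth_dir2")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  p1 <- df$p1
  p2 <- df$p2
  meg <- !is.na(p1) & !is.na(p2) & gt(p1, u) & lt(p2, l)
  peg <- !is.na(p1) & !is.na(p2) & lt(p1, l) & gt(p2, u)
  bi <- !is.na(p1) & !is.na(p2) &
    p1 >= l & p1 <= u & p2 >= l & p2 <= u
  status <- dplyr::case_when(
    !is.na(df$expression_detected) & !df$expression_detected ~
      "not_detectable",
    is.na(p1) | is.na(p2) ~ "undetermined",
    meg ~ "MEG",
    peg ~ "PEG",
    bi ~ "biallelic",
    TRUE ~ "undetermined"
  )
  mf1 <- p1        # direction-1 dam is LL1, so maternal fraction = p1
  mf2 <- 1 - p2
  binom_p <- function(k, n) {
    out <- rep(NA_real_, length(k))
    ok <- !is.na(k) & !is.na(n) & n > 0
    out[ok] <- mapply(function(k, n) binom.test(round(k), round(n))$p.value,
                      k[ok], n[ok])
    out
  }
  annot_p1 <- binom_p(p1 * df$pooled_depth_dir1, df$pooled_depth_dir1)
  annot_p2 <- binom_p(p2 * df$pooled_depth_dir2, df$pooled_depth_dir2)
  tibble::tibble(
    gene_id = df$gene_id,
    tissue = df$tissue,
    status = status,
    expressed_parent = dplyr::case_when(status == "MEG" ~ "maternal",
                                        status == "PEG" ~ "paternal",
                                        TRUE ~ "none"),
    expressed_parent_fraction_dir1 = dplyr::case_when(
      status == "MEG" ~ mf1, status == "PEG" ~ 1 - mf1, TRUE ~ NA_real_),
    expressed_parent_fraction_dir2 = dplyr::case_when(
      status == "MEG" ~ mf2, status == "PEG" ~ 1 - mf2, TRUE ~ NA_real_),
    maternal_fraction_dir1 = mf1,
    maternal_fraction_dir2 = mf2,
    p1 = p1, p2 = p2,
    flipped = meg | peg,
    binom_p_dir1 = annot_p1,
    binom_p_dir2 = annot_p2,
    evidence = sprintf(
      "n_snps=%s; depth_dir1=%s; depth_dir2=%s",
      df$n_informative_snps, df$pooled_depth_dir1, df$pooled_depth_dir2)
  )
}

#' Flag imprinted-XCI candidates among maternal calls on X/unplaced scaffolds
#'
#' Genes on the X chromosome or on unplaced scaffolds showing effectively
#' 100% maternal expression are re-labeled `xci_candidate` — the expected
#' signature of imprinted X inactivation (paternal X silenced), not of
#' autosomal imprinting — and are excluded from autosomal summaries. The
#' per-sample maternal fractions, when supplied, must all reach
#' `xci_maternal_min`; otherwise the gene keeps its MEG label and a
#' warning notes the near-miss.
#'
#' @param calls Calls tibble from [call_genes()].
#' @param genes Gene-model tibble supplying `chrom` per gene.
#' @param cfg A [caller_config()].
#' @param per_sample Optional per-sample gene maternal fractions (from
#'   [aggregate_gene()]); when absent the two pooled direction fractions
#'   are used.
#' @param xci_chroms Chromosome labels subject to the rule.
#' @return `calls` with a `chrom` column and updated statuses.
#' @export
flag_xci_candidates <- function(calls, genes, cfg = caller_config(),
                                per_sample = NULL,
                                xci_chroms = c("chrUn", "chrX")) {
  stopifnot(inherits(cfg, "caller_config"))
  out <- dplyr::left_join(
    calls, dplyr::distinct(genes, .data$gene_id, .data$chrom),
    by = "gene_id")
  min_mat <- if (!is.null(per_sample)) {
    ps <- dplyr::summarise(per_sample,
                           min_maternal = min(.data$maternal_fraction),
                           .by = c("gene_id", "tissue"))
    dplyr::left_join(out, ps, by = c("gene_id", "tissue"))$min_maternal
  } else {
    pmin(out$maternal_fraction_dir1, out$maternal_fraction_dir2)
  }
  on_xci_chrom <- out$chrom %in% xci_chroms & out$status == "MEG"
  promote <- on_xci_chrom & !is.na(min_mat) &
    min_mat >= cfg$xci_maternal_min
  near_miss <- on_xci_chrom & !promote
  if (any(near_miss)) {
    warning(sum(near_miss), " maternal call(s) on ",
            paste(xci_chroms, collapse = "/"),
            " below the XCI maternal floor; kept as MEG", call. = FALSE)
  }
  out$status[promote] <- "xci_candidate"
  out
}

#' Summarize imprinting calls per tissue and across tissues
#'
#' @param calls Calls tibble (after [flag_xci_candidates()] when XCI
#'   screening applies).
#' @return List with `per_tissue` (MEG/PEG/imprinted counts per tissue;
#'   XCI candidates tallied separately), `cross_tissue` (per gene: number
#'   of tissues imprinted / not detectable, concordance category), and
#'   `candidates` (gene_id, tissue, status for imprinted calls).
#' @export
summarize_calls <- function(calls) {
  imprinted <- c("MEG", "PEG")
  tissues <- sort(unique(calls$tissue))
  per_tissue <- tidyr::crossing(tissue = tissues) |>
    dplyr::left_join(
      calls |>
        dplyr::summarise(
          n_meg = sum(.data$status == "MEG"),
          n_peg = sum(.data$status == "PEG"),
          n_imprinted = sum(.data$status %in% imprinted),
          n_xci_candidate = sum(.data$status == "xci_candidate"),
          n_not_detectable = sum(.data$status == "not_detectable"),
          .by = "tissue"),
      by = "tissue") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("n_"),
                                ~ dplyr::coalesce(.x, 0L)))
  cross_tissue <- calls |>
    dplyr::summarise(
      n_tissues_imprinted = sum(.data$status %in% imprinted),
      n_tissues_not_detectable = sum(.data$status == "not_detectable"),
      n_tissues = dplyr::n(),
      .by = "gene_id") |>
    dplyr::mutate(category = dplyr::case_when(
      .data$n_tissues_imprinted == .data$n_tissues &
        .data$n_tissues > 1 ~ "imprinted_in_both",
      .data$n_tissues_imprinted >= 1 &
        .data$n_tissues_not_detectable ==
          .data$n_tissues - .data$n_tissues_imprinted ~
        "imprinted_where_detectable",
      .data$n_tissues_imprinted >= 1 ~ "imprinted_in_one",
      TRUE ~ "not_imprinted"))
  candidates <- calls |>
    dplyr::filter(.data$status %in% c(imprinted, "xci_candidate")) |>
    dplyr::select("gene_id", "tissue", "status", "expressed_parent")
  list(per_tissue = per_tissue, cross_tissue = cross_tissue,
       candidates = candidates)
}
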