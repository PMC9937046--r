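# Bisulfite clone methylation calling and promoter DMR classification.
#
# Bisulfite treatment converts unmethylated cytosines to uracil (read as
# T) and leaves methylated cytosines intact. At each reference CpG a
# retained C is a methylated call (M) and a T an unmethylated call (U);
# non-CpG cytosines, which should always convert, measure conversion
# efficiency. An allele-differentially methylated promoter shows ~50%
# aggregate methylation with the two parental alleles far apart — the
# hallmark of a DMR.

#' Call one clone's CpG methylation from its sequence
#'
#' The clone must align end-to-end with the reference region (same
#' length); degenerate C/T matching at converted positions is implied by
#' the calling rule, so no explicit alignment is performed.
#'
#' @param reference_region Reference DNA string (unconverted genomic
#'   sequence of the amplicon).
#' @param clone_sequence One sequenced clone, same length.
#' @param clone_id Identifier carried into the result.
#' @param allele_tag `"maternal"`, `"paternal"` or `"unknown"`.
#' @param min_conversion Clones whose non-CpG cytosine conversion rate is
#'   below this are flagged excluded (failed bisulfite conversion).
#' @return One-row tibble: clone_id, allele_tag, conversion_rate,
#'   excluded flag, then `cpg_<i>` call columns (`"M"`, `"U"` or `NA`).
#' @export
call_clone_from_sequence <- function(reference_region, clone_sequence,
                                     clone_id = "clone",
                                     allele_tag = "unknown",
                                     min_conversion = 0.95) {
  ref <- strsplit(toupper(reference_region), "")[[1]]
  clone <- strsplit(toupper(clone_sequence), "")[[1]]
  if (length(ref) != length(clone)) {
    stop("clone and reference lengths differ (",
         length(clone), " vs ", length(ref), ")", call. = FALSE)
  }
  cpg_c <- which(ref == "C" & c(ref[-1], "") == "G")
  if (length(cpg_c) == 0) {
    stop("reference region contains no CpG site", call. = FALSE)
  }
  noncpg_c <- setdiff(which(ref == "C"), cpg_c)
  calls <- dplyr::case_when(clone[cpg_c] == "C" ~ "M",
                            clone[cpg_c] == "T" ~ "U",
                            TRUE ~ NA_character_)
  informative <- clone[noncpg_c] %in% c("C", "T")
  conversion_rate <- if (sum(informative) == 0) {
    NA_real_
  } else {
    sum(clone[noncpg_c] == "T") / sum(informative)
  }
  excluded <- !is.na(conversion_rate) && conversion_rate < min_conversion
  out <- tibble::tibble(clone_id = clone_id, allele_tag = allele_tag,
                        conversion_rate = conversion_rate,
                        excluded = excluded)
  out[paste0("cpg_", seq_along(calls))] <- as.list(calls)
  out
}

#' Call a set of clones from FASTA sequences
#'
#' @param reference_region Reference DNA string.
#' @param clone_sequences Named character vector of clone sequences (names
#'   become clone ids).
#' @param allele_tags Optional named vector of allele tags per clone.
#' @param min_conversion Conversion-completeness threshold.
#' @return Clone tibble (one row per clone) with exclusion flags.
#' @export
call_clones_from_sequences <- function(reference_region, clone_sequences,
                                       allele_tags = NULL,
                                       min_conversion = 0.95) {
  ids <- names(clone_sequences) %||% paste0("clone", seq_along(clone_sequences))
  dplyr::bind_rows(lapply(seq_along(clone_sequences), function(i) {
    tag <- if (!is.null(allele_tags)) {
      allele_tags[[ids[i]]] %||% "unknown"
    } else {
      "unknown"
    }
    call_clone_from_sequence(reference_region, clone_sequences[[i]],
                             clone_id = ids[i], allele_tag = tag,
                             min_conversion = min_conversion)
  }))
}

#' Call bisulfite clones from FASTA files
#'
#' @param reference_fasta FASTA with the (unconverted) reference region;
#'   the first record is used.
#' @param clones_fasta FASTA of sequenced clones (record names become
#'   clone ids).
#' @param ... Passed to [call_clones_from_sequences()] (`allele_tags`,
#'   `min_conversion`).
#' @return Clone tibble, one row per clone.
#' @export
call_clones_from_fasta <- function(reference_fasta, clones_fasta, ...) {
  ref <- as.character(Biostrings::readDNAStringSet(reference_fasta))[[1]]
  clones <- as.character(Biostrings::readDNAStringSet(clones_fasta))
  call_clones_from_sequences(ref, clones, ...)
}

clone_call_matrix <- function(clones) {
  call_cols <- grep("^cpg_", names(clones), value = TRUE)
  as.matrix(clones[, call_cols, drop = FALSE])
}

#' Per-CpG methylation percentages and the region mean
#'
#' Missing calls never enter a denominator. The region mean is the mean
#' over CpG sites of the per-site percentage. Clones flagged `excluded`
#' (failed conversion) are dropped first.
#'
#' @param clones Clone tibble (from the sequence caller, the simulator,
#'   or [read_clone_matrix()]).
#' @return List with `cpg_sites` (index, percent_methylated in `[0,1]`,
#'   n_calls) and `region` (mean_percent, n_clones, n_cpgs). Zero passing
#'   clones give empty tables and a `reason`.
#' @export
cpg_percentages <- function(clones) {
  if ("excluded" %in% names(clones)) {
    clones <- dplyr::filter(clones, !.data$excluded)
  }
  if (nrow(clones) == 0) {
    return(list(cpg_sites = tibble::tibble(index = integer(),
                                           percent_methylated = numeric(),
                                           n_calls = integer()),
                region = tibble::tibble(mean_percent = NA_real_,
                                        n_clones = 0L, n_cpgs = 0L),
                reason = "no clones passed the conversion filter"))
  }
  m <- clone_call_matrix(clones)
  n_m <- colSums(m == "M", na.rm = TRUE)
  n_u <- colSums(m == "U", na.rm = TRUE)
  pct <- unname(ifelse(n_m + n_u > 0, n_m / (n_m + n_u), NA_real_))
  cpg_sites <- tibble::tibble(index = seq_along(pct),
                              percent_methylated = pct,
                              n_calls = as.integer(n_m + n_u))
  region <- tibble::tibble(
    mean_percent = mean(pct, na.rm = TRUE),
    n_clones = nrow(m),
    n_cpgs = ncol(m))
  list(cpg_sites = cpg_sites, region = region)
}

#' Partition clone methylation by parental allele tag
#'
#' @param clones Clone tibble with `allele_tag`; untagged clones are
#'   excluded from the partition (but still count toward the region mean
#'   computed by [cpg_percentages()]).
#' @return Tibble with one row per present allele: pooled methylation
#'   fraction and call count; `one_sided` is `TRUE` when only one allele
#'   is represented, and the result is empty (with a message) when no
#'   clone carries a tag.
#' @export
partition_by_allele <- function(clones) {
  if ("excluded" %in% names(clones)) {
    clones <- dplyr::filter(clones, !.data$excluded)
  }
  tagged <- dplyr::filter(clones,
                          .data$allele_tag %in% c("maternal", "paternal"))
  if (nrow(tagged) == 0) {
    message("no allele-tagged clones; allele partition unknown")
    return(tibble::tibble(allele = character(), mean_methylation = numeric(),
                          n_calls = integer(), n_clones = integer(),
                          one_sided = logical()))
  }
  res <- tagged |>
    dplyr::group_by(allele = .data$allele_tag) |>
    dplyr::group_modify(function(d, key) {
      m <- clone_call_matrix(d)
      n_m <- sum(m == "M", na.rm = TRUE)
      n_u <- sum(m == "U", na.rm = TRUE)
      tibble::tibble(mean_methylation = n_m / (n_m + n_u),
                     n_calls = as.integer(n_m + n_u),
                     n_clones = nrow(d))
    }) |>
    dplyr::ungroup()
  res$one_sided <- dplyr::n_distinct(res$allele) == 1L
  res
}

#' Classify a promoter region as DMR / methylated / unmethylated
#'
#' Screening logic: a region mean below `low` is unmethylated, above
#' `high` methylated. A mean inside the intermediate `band` is the
#' candidate DMR zone (allele-differential methylation averages to ~50%);
#' it is confirmed as a DMR only when per-allele means differ by at least
#' `allele_diff_min`, otherwise it stays `intermediate_unresolved` (as do
#' means between the extremes and the band).
#'
#' @param region One-row region tibble from [cpg_percentages()] (or any
#'   list with `mean_percent`).
#' @param per_allele Optional allele partition from
#'   [partition_by_allele()].
#' @param band Intermediate screening band (default `c(0.30, 0.70)`).
#' @param allele_diff_min Minimum |maternal - paternal| methylation
#'   difference for a confirmed DMR.
#' @param low,high Unmethylated / methylated screening cutoffs.
#' @return One-row tibble: classification, methylated_parent,
#'   mean_percent, per-allele means.
#' @export
classify_dmr <- function(region, per_allele = NULL,
                         band = c(0.30, 0.70), allele_diff_min = 0.40,
                         low = 0.20, high = 0.80) {
  mean_pct <- region$mean_percent[[1]]
  mat <- pat <- NA_real_
  if (!is.null(per_allele) && nrow(per_allele) > 0) {
    mat <- per_allele$mean_methylation[per_allele$allele == "maternal"][1]
    pat <- per_allele$mean_methylation[per_allele$allele == "paternal"][1]
  }
  diff <- abs(mat - pat)
  classification <- dplyr::case_when(
    is.na(mean_pct) ~ "intermediate_unresolved",
    mean_pct < low ~ "unmethylated",
    mean_pct > high ~ "methylated",
    mean_pct >= band[1] & mean_pct <= band[2] &
      !is.na(diff) & diff >= allele_diff_min ~ "DMR",
    TRUE ~ "intermediate_unresolved")
  methylated_parent <- if (classification == "DMR") {
    if (mat > pat) "maternal" else "paternal"
  } else if (classification == "methylated") {
    "none"
  } else {
    "unknown"
  }
  tibble::tibble(classification = classification,
                 methylated_parent = methylated_parent,
                 mean_percent = mean_pct,
                 maternal_mean = mat, paternal_mean = pat)
}

#' Text lollipop rendering of a clone matrix
#'
#' One line per clone: filled circles for methylated CpGs, open circles
#' for unmethylated, `.` for missing — the conventional bisulfite-cloning
#' figure, in plain text.
#'
#' @param clones Clone tibble.
#' @param filled,open Glyphs for M and U calls.
#' @return Character vector (one element per clone), invisibly printed
#'   with `cat()` friendliness.
#' @export
lollipop_text <- function(clones, filled = "●", open = "○") {
  m <- clone_call_matrix(clones)
  glyph <- matrix(".", nrow(m), ncol(m))
  glyph[m == "M"] <- filled
  glyph[m == "U"] <- open
  lines <- apply(glyph, 1, paste, collapse = " ")
  tags <- if ("allele_tag" %in% names(clones)) {
    sprintf("%-9s", clones$allele_tag)
  } else {
    ""
  }
  paste0(format(clones$clone_id), "  ", tags, " ", lines)
}
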