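# Readers and writers for the pipeline's external formats.
#
# Allele-count TSV dialect (wide): chrom, pos (1-based), ref, alt, then
# one "<sample_id>.ref" and "<sample_id>.alt" column pair per sample.
# Internally counts are kept long: one row per SNP x sample.

#' Load allele counts from TSV or VCF together with sample metadata
#'
#' @param path Allele-count TSV in the wide dialect above, or a VCF whose
#'   per-sample FORMAT includes allelic depth (`AD`, "ref,alt").
#' @param sample_sheet Path to a sample-metadata TSV (columns sample_id,
#'   role, stock, dam_stock, sire_stock, tissue) or an equivalent tibble.
#' @return List with `counts` (long tibble: chrom, pos, ref, alt,
#'   sample_id, ref_count, alt_count) and `meta`.
#' @export
load_allele_counts <- function(path, sample_sheet) {
  meta <- if (is.character(sample_sheet)) {
    readr::read_tsv(sample_sheet, show_col_types = FALSE)
  } else {
    tibble::as_tibble(sample_sheet)
  }
  required <- c("sample_id", "role", "tissue")
  if (!all(required %in% names(meta))) {
    stop("sample sheet must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  counts <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_vcf_allele_counts(path)
  } else {
    read_tsv_allele_counts(path)
  }
  missing <- setdiff(meta$sample_id, unique(counts$sample_id))
  if (length(missing) > 0) {
    stop("samples declared in the sheet but absent from the counts: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  counts <- dplyr::filter(counts, .data$sample_id %in% meta$sample_id)
  validate_counts(counts)
  list(counts = counts, meta = meta)
}

read_tsv_allele_counts <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  fixed <- c("chrom", "pos", "ref", "alt")
  if (!all(fixed %in% names(wide))) {
    stop("allele-count TSV must start with columns chrom, pos, ref, alt",
         call. = FALSE)
  }
  count_cols <- setdiff(names(wide), fixed)
  bad <- count_cols[!grepl("\\.(ref|alt)$", count_cols)]
  if (length(bad) > 0) {
    stop("count columns must be named <sample_id>.ref / <sample_id>.alt; ",
         "offending: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(!vapply(wide[count_cols],
                  function(x) is.numeric(x) && all(x == as.integer(x)),
                  TRUE))) {
    stop("allele counts must be integers", call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    wide, cols = dplyr::all_of(count_cols),
    names_to = c("sample_id", "allele"), names_pattern = "^(.*)\\.(ref|alt)$",
    values_to = "count")
  tidyr::pivot_wider(long, names_from = "allele", values_from = "count",
                     names_glue = "{allele}_count") |>
    dplyr::mutate(pos = as.integer(.data$pos),
                  ref_count = as.integer(.data$ref_count),
                  alt_count = as.integer(.data$alt_count))
}

read_vcf_allele_counts <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  fix <- tibble::tibble(
    chrom = vcfR::getCHROM(vcf),
    pos = as.integer(vcfR::getPOS(vcf)),
    ref = vcfR::getREF(vcf),
    alt = vcfR::getALT(vcf)
  )
  long <- tidyr::crossing(idx = seq_len(nrow(fix)),
                          sample_id = colnames(ad)) |>
    dplyr::arrange(.data$idx)
  ad_flat <- ad[cbind(long$idx, match(long$sample_id, colnames(ad)))]
  parts <- strsplit(ifelse(is.na(ad_flat), "0,0", ad_flat), ",",
                    fixed = TRUE)
  dplyr::bind_cols(fix[long$idx, ], dplyr::select(long, "sample_id")) |>
    dplyr::mutate(
      ref_count = as.integer(vapply(parts, `[`, "", 1L)),
      alt_count = as.integer(vapply(parts, function(p) {
        if (length(p) >= 2) p[2] else "0"
      }, ""))
    )
}

validate_counts <- function(counts) {
  dup <- counts |>
    dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::count(.data$chrom, .data$pos) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicated SNP positions: ",
         paste0(dup$chrom, ":", dup$pos, collapse = ", "), call. = FALSE)
  }
  if (any(counts$pos < 1)) stop("SNP positions must be >= 1", call. = FALSE)
  if (any(counts$ref == counts$alt)) {
    stop("ref and alt alleles must differ", call. = FALSE)
  }
  if (any(counts$ref_count < 0 | counts$alt_count < 0)) {
    stop("allele counts must be non-negative", call. = FALSE)
  }
  invisible(counts)
}

#' Write allele counts in the wide TSV dialect
#'
#' @param counts Long counts tibble.
#' @param path Output path.
#' @export
write_allele_counts <- function(counts, path) {
  wide <- counts |>
    tidyr::pivot_longer(c("ref_count", "alt_count"), names_to = "allele",
                        values_to = "count") |>
    dplyr::mutate(allele = sub("_count$", "", .data$allele)) |>
    tidyr::pivot_wider(names_from = c("sample_id", "allele"),
                       values_from = "count", names_sep = ".") |>
    dplyr::arrange(.data$chrom, .data$pos)
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read repeat intervals from a BED file
#'
#' BED is 0-based half-open; intervals are sorted (with a warning when the
#' input was not) and returned as a tibble ready for [mask_set()].
#'
#' @param path BED file path.
#' @return Tibble with chrom, start (0-based), end.
#' @export
read_repeat_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         comment = "#")
  out <- tibble::tibble(chrom = as.character(bed[[1]]),
                        start = as.integer(bed[[2]]),
                        end = as.integer(bed[[3]]))
  if (is.unsorted(order(out$chrom, out$start))) {
    # keep going: masking only needs interval membership
    warning("BED intervals were not sorted; sorting", call. = FALSE)
  }
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Read gene models (genes + exons) from GFF3/GTF
#'
#' @param path GFF3 or GTF file.
#' @return List of tibbles `genes` (gene_id, chrom, start, end, strand)
#'   and `exons` (gene_id, chrom, start, end).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  df <- tibble::as_tibble(as.data.frame(gr))
  if (!"gene_id" %in% names(df)) {
    if ("ID" %in% names(df)) {
      df$gene_id <- sub("^gene:", "", as.character(df$ID))
    } else {
      stop("gene models need a gene_id (or ID) attribute", call. = FALSE)
    }
  }
  if ("Parent" %in% names(df)) {
    parent <- vapply(df$Parent, function(p) {
      if (length(p) == 0) NA_character_ else as.character(p[1])
    }, "")
    df$gene_id <- ifelse(df$type == "exon" & !is.na(parent),
                         sub("^gene:", "", parent), df$gene_id)
  }
  genes <- df |>
    dplyr::filter(.data$type == "gene") |>
    dplyr::transmute(gene_id = as.character(.data$gene_id),
                     chrom = as.character(.data$seqnames),
                     start = .data$start, end = .data$end,
                     strand = as.character(.data$strand))
  exons <- df |>
    dplyr::filter(.data$type == "exon") |>
    dplyr::transmute(gene_id = as.character(.data$gene_id),
                     chrom = as.character(.data$seqnames),
                     start = .data$start, end = .data$end)
  if (nrow(exons) == 0) {
    exons <- dplyr::select(genes, "gene_id", "chrom", "start", "end")
  }
  list(genes = genes, exons = exons)
}

#' Write gene models to GFF3
#'
#' @param genes,exons Gene-model tibbles as produced by
#'   [simulate_cross_dataset()].
#' @param path Output GFF3 path.
#' @export
write_gene_models <- function(genes, exons, path) {
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand,
    type = "gene", ID = paste0("gene:", genes$gene_id),
    gene_id = genes$gene_id)
  exon_gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(exons$start, exons$end),
    strand = genes$strand[match(exons$gene_id, genes$gene_id)],
    type = "exon", ID = NA_character_,
    gene_id = exons$gene_id)
  S4Vectors::mcols(exon_gr)$Parent <- paste0("gene:", exons$gene_id)
  rtracklayer::export(c(gene_gr, exon_gr), path, format = "gff3")
  invisible(path)
}

#' Read a bisulfite clone matrix TSV
#'
#' Columns: clone_id, allele_tag (maternal/paternal/unknown), then one
#' column per CpG with calls M (methylated), U (unmethylated) or `.`
#' (missing).
#'
#' @param path TSV path.
#' @return Clone tibble with `NA` for missing calls.
#' @export
read_clone_matrix <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  call_cols <- setdiff(names(m), c("clone_id", "allele_tag"))
  m[call_cols] <- lapply(m[call_cols], function(x) {
    x[x == "."] <- NA_character_
    if (!all(x %in% c("M", "U", NA_character_))) {
      stop("clone matrix calls must be M, U or .", call. = FALSE)
    }
    x
  })
  m
}

#' Write a bisulfite clone matrix TSV
#'
#' @param clones Clone tibble.
#' @param path Output path.
#' @export
write_clone_matrix <- function(clones, path) {
  out <- clones
  call_cols <- setdiff(names(out), c("clone_id", "allele_tag"))
  out[call_cols] <- lapply(out[call_cols], function(x) {
    ifelse(is.na(x), ".", x)
  })
  readr::write_tsv(out, path)
  invisible(path)
}
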