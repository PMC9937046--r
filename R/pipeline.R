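# End-to-end pipeline driver over a validated configuration.
#
# Stage order: simulate -> discover -> genotype -> informativeness ->
# masks -> allelic ratios -> gene aggregation -> expression gate ->
# imprinting calls -> XCI flag -> summary -> genome estimate ->
# (optional) promoter methylation. All thresholds are echoed to a
# machine-readable JSON-lines log so a run is auditable.

pipeline_schema <- function() {
  list(
    seed = NULL,
    out_dir = NULL,
    simulate = names(formals(sim_config)),
    thresholds = c("min_pooled_depth", "min_sample_depth", "min_f1_covered",
                   "upper", "lower", "fpkm_min", "xci_maternal_min",
                   "boundary_distance"),
    methylation = c("enabled", "n_clones", "n_cpgs", "maternal_meth_prob",
                    "paternal_meth_prob", "conversion_failure_rate"),
    estimate = c("conf")
  )
}

validate_pipeline_config <- function(config) {
  pipeline_schema <- pipeline_schema()
  unknown <- setdiff(names(config), names(pipeline_schema))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (section in c("simulate", "thresholds", "methylation", "estimate")) {
    if (!is.null(config[[section]])) {
      bad <- setdiff(names(config[[section]]), pipeline_schema[[section]])
      if (length(bad) > 0) {
        stop("unknown configuration key(s) in `", section, "`: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  invisible(config)
}

#' Run the full reciprocal-cross imprinting pipeline
#'
#' @param config A YAML file path or a list. Sections: `seed`, `out_dir`,
#'   `simulate` (arguments of [sim_config()]), `thresholds`
#'   (min_pooled_depth, min_sample_depth, min_f1_covered, upper, lower,
#'   fpkm_min, xci_maternal_min, boundary_distance), `methylation`
#'   (enabled + [simulate_bisulfite_clones()] parameters), `estimate`
#'   (conf). Unknown keys are rejected by name.
#' @param out_dir Output directory (overrides the config entry).
#' @return Invisibly, a list with every intermediate table plus the
#'   genome estimate; all tables are also written as TSV/JSON under
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop(
    "an output directory is required (config `out_dir` or argument)",
    call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- modifyList(list(min_pooled_depth = 40, min_sample_depth = 8,
                        min_f1_covered = 3, upper = 0.65, lower = 0.35,
                        fpkm_min = 1.0, xci_maternal_min = 0.99,
                        boundary_distance = 5),
                   config$thresholds %||% list())
  cfg <- caller_config(upper = th$upper, lower = th$lower,
                       xci_maternal_min = th$xci_maternal_min)

  log_path <- file.path(out_dir, "run_log.jsonl")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  log_line <- function(stage, ...) {
    writeLines(jsonlite::toJSON(c(list(stage = stage), list(...)),
                                auto_unbox = TRUE, digits = NA), log_con)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      log_line(stage, status = "failed", error = conditionMessage(e))
      stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log_line("config", package_version = as.character(
    utils::packageVersion("imprintase")),
    seed = config$seed %||% NA, thresholds = th)

  ## simulate -------------------------------------------------------------
  sim_args <- config$simulate %||% list()
  if (!is.null(config$seed) && is.null(sim_args$seed)) {
    sim_args$seed <- config$seed
  }
  sim <- run_stage("simulate", {
    simulate_cross_dataset(do.call(sim_config, sim_args))
  })
  log_line("simulate", n_genes = nrow(sim$genes),
           n_snps = dplyr::n_distinct(paste(sim$sites$chrom,
                                            sim$sites$pos)))

  ## filter ---------------------------------------------------------------
  candidates <- run_stage("filter", {
    discover_candidate_snps(sim$counts, th$min_pooled_depth)
  })
  masks <- mask_set(exons = sim$exons,
                    boundary_distance = th$boundary_distance)
  candidates <- run_stage("filter", apply_masks(candidates, masks))
  genotypes <- run_stage("filter", {
    genotype_stocks(candidates, sim$meta, min_depth = th$min_sample_depth)
  })
  informative <- run_stage("filter", {
    assess_informativeness(genotypes, candidates, sim$meta,
                           min_f1_covered = th$min_f1_covered,
                           min_depth = th$min_sample_depth)
  })
  n_informative <- informative |>
    dplyr::filter(.data$informative) |>
    dplyr::distinct(.data$chrom, .data$pos) |>
    nrow()
  log_line("filter",
           n_candidate_snps = dplyr::n_distinct(paste(candidates$chrom,
                                                      candidates$pos)),
           n_informative_snps = n_informative)

  ## ASE ------------------------------------------------------------------
  ratios <- run_stage("ase", {
    snp_allelic_ratios(candidates, sim$meta, informative,
                       min_depth = th$min_sample_depth)
  })
  agg <- run_stage("ase", aggregate_gene(ratios, sim$genes))
  gene_ase <- run_stage("ase", {
    expression_gate(agg$gene_ase, sim$expression, threshold = th$fpkm_min)
  })
  log_line("ase", n_genes_with_ase = dplyr::n_distinct(gene_ase$gene_id))

  ## call -----------------------------------------------------------------
  calls <- run_stage("call", call_genes(gene_ase, cfg))
  calls <- run_stage("call", {
    flag_xci_candidates(calls, sim$genes, cfg, per_sample = agg$per_sample)
  })
  summary <- run_stage("call", summarize_calls(calls))
  log_line("call", per_tissue = summary$per_tissue)

  ## estimate -------------------------------------------------------------
  estimate <- run_stage("estimate", {
    expressed <- sim$expression |>
      dplyr::summarise(fpkm = mean(.data$fpkm), .by = "gene_id") |>
      dplyr::filter(.data$fpkm >= th$fpkm_min)
    autosomal_expressed <- expressed |>
      dplyr::semi_join(dplyr::filter(sim$genes,
                                     !.data$chrom %in% c("chrUn", "chrX")),
                       by = "gene_id")
    covered <- intersect(unique(gene_ase$gene_id),
                         autosomal_expressed$gene_id)
    cov <- coverage_fraction(covered, autosomal_expressed$gene_id)
    detected <- calls |>
      dplyr::filter(.data$status %in% c("MEG", "PEG"),
                    !.data$chrom %in% c("chrUn", "chrX")) |>
      dplyr::distinct(.data$gene_id) |>
      nrow()
    extrapolate_total(detected, cov, n_covered = length(covered),
                      conf = (config$estimate %||% list())$conf %||% 0.95)
  })
  log_line("estimate", n_detected = estimate$n_detected,
           coverage = estimate$coverage_fraction,
           extrapolated_total = estimate$extrapolated_total)

  ## methylation (optional) ----------------------------------------------
  methylation <- NULL
  meth_cfg <- config$methylation %||% list()
  if (isTRUE(meth_cfg$enabled)) {
    methylation <- run_stage("methylation", {
      clones <- simulate_bisulfite_clones(
        n_clones = meth_cfg$n_clones %||% 20,
        n_cpgs = meth_cfg$n_cpgs %||% 12,
        maternal_meth_prob = meth_cfg$maternal_meth_prob %||% 0.96,
        paternal_meth_prob = meth_cfg$paternal_meth_prob %||% 0.18,
        conversion_failure_rate = meth_cfg$conversion_failure_rate %||% 0,
        seed = (config$seed %||% 1L) + 1L)
      pct <- cpg_percentages(clones$clones)
      allele <- partition_by_allele(clones$clones)
      dmr <- classify_dmr(pct$region, allele)
      list(clones = clones$clones, cpg_sites = pct$cpg_sites,
           region = pct$region, per_allele = allele, dmr = dmr)
    })
    log_line("methylation", classification = methylation$dmr$classification,
             mean_percent = methylation$dmr$mean_percent)
  }

  ## outputs --------------------------------------------------------------
  readr::write_tsv(informative, file.path(out_dir, "informative_snps.tsv"))
  readr::write_tsv(ratios, file.path(out_dir, "snp_ratios.tsv"))
  readr::write_tsv(gene_ase, file.path(out_dir, "gene_ase.tsv"))
  readr::write_tsv(calls, file.path(out_dir, "calls.tsv"))
  readr::write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
  jsonlite::write_json(
    list(per_tissue = summary$per_tissue,
         cross_tissue_categories =
           as.list(table(summary$cross_tissue$category)),
         estimate = list(n_detected = estimate$n_detected,
                         coverage_fraction = estimate$coverage_fraction,
                         extrapolated_total = estimate$extrapolated_total,
                         interval = unname(estimate$interval))),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(methylation)) {
    readr::write_tsv(methylation$cpg_sites,
                     file.path(out_dir, "methylation_cpg_sites.tsv"))
    readr::write_tsv(methylation$dmr, file.path(out_dir, "dmr_call.tsv"))
  }
  log_line("done", status = "success")
  invisible(list(sim = sim, candidates = candidates,
                 genotypes = genotypes, informative = informative,
                 ratios = ratios, gene_ase = gene_ase, calls = calls,
                 per_sample = agg$per_sample, summary = summary,
                 estimate = estimate, methylation = methylation,
                 thresholds = th))
}
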