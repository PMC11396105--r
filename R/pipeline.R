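#' Pipeline configuration with the canonical thresholds
#'
#' Collects every stage threshold in one place. The defaults are the
#' published operating points of each stage: variant hard filter
#' QD < 2 / FS > 60 / MQ < 40 with GQ >= 20; reciprocal-best-hit e-value
#' cutoff 1e-5; allelic-bias gates ratio >= 2 (or <= 0.5) with q <= 0.01 in
#' every replicate; DMR window 200 bp, per-site coverage >= 4, per-context
#' site/delta minimums of 5/0.25 (CG, CHG), 15/0.15 (CHH) and 20/0.2
#' (pooled C) at q <= 0.05; DEG thresholds adjusted p < 0.05 and
#' |log2FC| >= 1.
#'
#' @param sim A [cross_sim_config()] used by the simulate stage.
#' @param vcf_min_gq Minimum parental genotype quality.
#' @param rbh_evalue E-value cutoff for ortholog pairing.
#' @param ase_min_total,ase_alpha_q,ase_ratio_hi,ase_ratio_lo Bias-test
#'   gates, see [test_bias()].
#' @param ase_mode Replicate handling for [test_bias()].
#' @param mc_conversion_error Bisulfite non-conversion rate for
#'   [call_methylcytosines()].
#' @param dmr_window,dmr_min_cov,dmr_alpha_q DMR caller parameters.
#' @param dmc_min_delta Minimum |delta| for a DMC call.
#' @param deg_alpha,deg_lfc_min DEG thresholds.
#' @param fpkm_transcriptome_genes The simulated gene panel is treated as a
#'   random sample from a transcriptome of this many genes when computing
#'   FPKM (the per-sample library size is extrapolated accordingly), so
#'   FPKM values land on the absolute scale the expression bins assume.
#'   Set to `NULL` to use raw column totals.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = cross_sim_config(),
                            vcf_min_gq = 20,
                            rbh_evalue = 1e-5,
                            ase_min_total = 10,
                            ase_alpha_q = 0.01,
                            ase_ratio_hi = 2,
                            ase_ratio_lo = 0.5,
                            ase_mode = "per_replicate",
                            mc_conversion_error = 0.01,
                            dmr_window = 200L,
                            dmr_min_cov = 4L,
                            dmr_alpha_q = 0.05,
                            dmc_min_delta = 0.25,
                            deg_alpha = 0.05,
                            deg_lfc_min = 1,
                            fpkm_transcriptome_genes = 20000) {
  stopifnot(inherits(sim, "cross_sim_config"))
  structure(as.list(environment()), class = "pipeline_config")
}

pipeline_stages <- function() {
  c("simulate", "diagnostics", "orthologs", "ase", "methylation", "dmr",
    "dmc", "expression", "integrate", "report")
}

require_stage <- function(results, need, for_stage) {
  if (is.null(results[[need]])) {
    abort(sprintf(
      "Stage \"%s\" requires the \"%s\" stage; add it to `stages` (or supply its output).",
      for_stage, need),
      class = "hybridscope_dependency_error")
  }
  invisible(TRUE)
}

#' Run the hybrid-cross analysis end to end
#'
#' Executes the requested stages in dependency order on a simulated (or
#' supplied) hybrid-cross dataset: diagnostic-SNP selection from the
#' parental VCF, ortholog pairing, allele-bias testing, methylation levels
#' and DMR/DMC calling, DEG calling, methylome-transcriptome integration,
#' and a machine-readable report that echoes the configuration and — when
#' ground truth is available — the recovery of every planted effect. The
#' default stage list covers the whole pipeline except the site-level DMC
#' scan, which is opt-in (add `"dmc"`).
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages to run, a subset of
#'   `"simulate"`, `"diagnostics"`, `"orthologs"`, `"ase"`,
#'   `"methylation"`, `"dmr"`, `"dmc"`, `"expression"`, `"integrate"`,
#'   `"report"`.
#' @param sim Optional pre-built `hybrid_cross_sim`; replaces the simulate
#'   stage.
#' @param dir Directory for the simulated files.
#' @return A `hybridscope_run` list holding each stage's output and the
#'   `report`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = setdiff(pipeline_stages(), "dmc"),
                         sim = NULL,
                         dir = tempfile("hybridscope_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(stages, pipeline_stages())
  if (length(bad)) {
    abort(sprintf("Unknown stage(s): %s.", paste(bad, collapse = ", ")),
          class = "hybridscope_config_error")
  }
  stages <- intersect(pipeline_stages(), stages)  # dependency order
  res <- list(config = config)

  if (!is.null(sim)) {
    res$sim <- sim
  } else if ("simulate" %in% stages) {
    res$sim <- simulate_cross(config$sim, dir = dir)
  }

  if ("diagnostics" %in% stages) {
    require_stage(res, "sim", "diagnostics")
    variants <- read_parent_vcf(res$sim$paths$vcf)
    passing <- hard_filter(variants, min_gq = config$vcf_min_gq)
    diag <- select_diagnostic(passing, reference_side = "paternal")
    gm <- as_gene_models(res$sim)
    res$diagnostics <- assign_to_genes(diag, gm)
    res$gene_models <- gm
  }

  if ("orthologs" %in% stages) {
    require_stage(res, "sim", "orthologs")
    res$orthologs <- reciprocal_best_hits(
      res$sim$tables$hits_ab, res$sim$tables$hits_ba,
      evalue_cutoff = config$rbh_evalue)
  }

  if ("ase" %in% stages) {
    require_stage(res, "diagnostics", "ase")
    counts <- count_alleles(res$sim$tables$allele_depths,
                            diagnostics = res$diagnostics)
    res$allele_counts <- counts
    res$ase <- test_bias(counts,
                         min_total = config$ase_min_total,
                         alpha_q = config$ase_alpha_q,
                         ratio_hi = config$ase_ratio_hi,
                         ratio_lo = config$ase_ratio_lo,
                         mode = config$ase_mode)
  }

  if ("methylation" %in% stages) {
    require_stage(res, "sim", "methylation")
    meth <- res$sim$tables$meth
    res$methylation <- list(
      mc_hybrid = call_methylcytosines(
        meth$hybrid, conversion_error = config$mc_conversion_error),
      levels_genome = bind_rows(
        mutate(methylation_levels(meth$hybrid), group = "hybrid"),
        mutate(methylation_levels(meth$maternal), group = "maternal")),
      levels_by_gene = methylation_levels(
        meth$hybrid, gene_models = as_gene_models(res$sim),
        scope = "gene_region"))
  }

  if ("dmr" %in% stages) {
    require_stage(res, "sim", "dmr")
    res$dmr <- call_dmrs(res$sim$tables$meth$hybrid,
                         res$sim$tables$meth$maternal,
                         window = config$dmr_window,
                         min_cov = config$dmr_min_cov,
                         alpha_q = config$dmr_alpha_q)
    res$dmgs <- annotate_dmr_genes(res$dmr, as_gene_models(res$sim))
  }

  if ("dmc" %in% stages) {
    require_stage(res, "sim", "dmc")
    res$dmc <- call_dmcs(res$sim$tables$meth$hybrid,
                         res$sim$tables$meth$maternal,
                         min_cov = config$dmr_min_cov,
                         min_delta = config$dmc_min_delta,
                         alpha_q = config$dmr_alpha_q)
  }

  if ("expression" %in% stages) {
    require_stage(res, "sim", "expression")
    counts <- res$sim$tables$counts
    samples <- setdiff(names(counts), "gene_id")
    groups <- setNames(sub("_[0-9]+$", "", samples), samples)
    lengths <- select(res$sim$genes, "gene_id", "length")
    lib <- NULL
    if (!is.null(config$fpkm_transcriptome_genes)) {
      lib <- vapply(counts[samples], sum, numeric(1)) *
        config$fpkm_transcriptome_genes / nrow(counts)
    }
    res$fpkm <- compute_fpkm(counts, lengths, library_sizes = lib)
    res$degs <- call_degs(counts, groups,
                          alpha = config$deg_alpha,
                          lfc_min = config$deg_lfc_min)
  }

  if ("integrate" %in% stages) {
    require_stage(res, "degs", "integrate")
    require_stage(res, "dmgs", "integrate")
    mean_fpkm <- res$fpkm |>
      filter(grepl("^hybrid", .data$sample)) |>
      group_by(.data$gene_id) |>
      summarise(fpkm = mean(.data$fpkm), .groups = "drop")
    region_levels <- if (!is.null(res$methylation)) {
      res$methylation$levels_by_gene
    } else {
      methylation_levels(res$sim$tables$meth$hybrid,
                         gene_models = as_gene_models(res$sim),
                         scope = "gene_region")
    }
    res$integration <- list(
      bins = bin_expression(mean_fpkm),
      meth_by_bin = methylation_by_bin(mean_fpkm, region_levels),
      common = common_genes(res$degs, res$dmgs))
  }

  if ("report" %in% stages) {
    res$report <- build_report(res)
  }
  structure(res, class = "hybridscope_run")
}

#' @export
print.hybridscope_run <- function(x, ...) {
  cat("<hybridscope_run> stages:",
      paste(intersect(pipeline_stages(),
                      c(names(x), if (!is.null(x$sim)) "simulate")),
            collapse = ", "), "\n")
  invisible(x)
}

# Ground-truth recovery of every planted effect; only meaningful for
# simulated data where the truth manifest exists.
recovery_stats <- function(res) {
  truth <- res$sim$truth
  out <- list()
  if (!is.null(res$ase)) {
    calls <- as_tibble(res$ase) |>
      select("gene_id", "classification")
    joined <- left_join(truth$biased_genes, calls, by = "gene_id") |>
      mutate(classification = dplyr::coalesce(.data$classification,
                                              "unbiased"))
    planted <- filter(joined, .data$bias != "none")
    nulls <- filter(joined, .data$bias == "none")
    out$ase_sensitivity <-
      if (nrow(planted)) mean(planted$classification == planted$bias)
      else NA_real_
    out$ase_false_bias_rate <-
      if (nrow(nulls)) mean(nulls$classification != "unbiased")
      else NA_real_
  }
  if (!is.null(res$dmr)) {
    planted <- truth$dmr_windows
    calls <- as_tibble(res$dmr)
    hit <- inner_join(
      planted,
      select(calls, "chrom", "start", "context", "status"),
      by = c("chrom", "start", "context")) |>
      filter(.data$status == .data$direction)
    out$dmr_sensitivity <-
      if (nrow(planted)) nrow(distinct(hit, .data$chrom, .data$start,
                                       .data$context)) / nrow(planted)
      else NA_real_
    null_windows <- calls |>
      filter(.data$tested) |>
      anti_join(planted, by = c("chrom", "start", "context"))
    out$dmr_false_rate <-
      if (nrow(null_windows)) mean(null_windows$status != "none")
      else NA_real_
  }
  if (!is.null(res$degs)) {
    joined <- left_join(truth$deg_genes, as_tibble(res$degs),
                        by = "gene_id", suffix = c("_true", "_called"))
    planted <- filter(joined, .data$status_true != "ns")
    out$deg_sensitivity <-
      if (nrow(planted)) mean(planted$status_called == planted$status_true)
      else NA_real_
  }
  out
}

build_report <- function(res) {
  cfg <- res$config
  report <- list(
    config = modifyList(lapply(unclass(cfg), function(x) {
      if (inherits(x, "cross_sim_config")) unclass(x) else x
    }), list()),
    stages = list())
  if (!is.null(res$diagnostics)) {
    report$stages$diagnostics <- list(
      n_diagnostic_snps = nrow(res$diagnostics),
      n_assigned = sum(!is.na(res$diagnostics$gene_id)),
      n_ambiguous = sum(res$diagnostics$ambiguous))
  }
  if (!is.null(res$orthologs)) {
    report$stages$orthologs <- list(n_pairs = nrow(res$orthologs))
  }
  if (!is.null(res$ase)) {
    report$stages$ase <- as.list(glance(res$ase))
  }
  if (!is.null(res$dmr)) {
    report$stages$dmr <- glance(res$dmr)
    report$stages$dmgs <- list(
      n_dmgs = dplyr::n_distinct(res$dmgs$gene_id))
  }
  if (!is.null(res$dmc)) {
    report$stages$dmc <- list(
      n_sites = nrow(res$dmc),
      n_dmcs = sum(res$dmc$status != "none"))
  }
  if (!is.null(res$degs)) {
    report$stages$expression <- as.list(glance(res$degs))
  }
  if (!is.null(res$integration)) {
    report$stages$integration <- as.list(glance(res$integration$common))
    report$stages$correlation <- res$integration$meth_by_bin$correlation
  }
  if (!is.null(res$sim) && !is.null(res$sim$truth)) {
    report$recovery <- recovery_stats(res)
  }
  structure(report, class = "hybridscope_report")
}

#' Write a pipeline report as JSON
#'
#' @param report A `hybridscope_report` (the `report` element of a
#'   [run_pipeline()] result).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @export
print.hybridscope_report <- function(x, ...) {
  cat("<hybridscope_report>\n")
  utils::str(x$stages, max.level = 2, give.attr = FALSE)
  if (!is.null(x$recovery)) {
    cat("recovery:\n")
    utils::str(x$recovery, give.attr = FALSE)
  }
  invisible(x)
}
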