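#' Bin genes by expression level
#'
#' Assigns each gene to one of the four canonical expression classes:
#' non-expressed (RPKM <= 1), low (1 < RPKM <= 10), middle
#' (10 < RPKM <= 100) and high (RPKM > 100). The bins partition every
#' non-negative value; boundaries follow the half-open pattern, so RPKM = 1
#' is `non` and RPKM = 10 is `low`.
#'
#' @param expr Tibble with gene_id and an expression column.
#' @param value Name of the expression column (default `"fpkm"`).
#' @return `expr` with an ordered factor column `bin`.
#' @export
bin_expression <- function(expr, value = "fpkm") {
  check_cols(expr, c("gene_id", value), "expression table")
  v <- expr[[value]]
  if (any(v < 0, na.rm = TRUE)) {
    abort("Expression values must be non-negative.",
          class = "hybridscope_config_error")
  }
  mutate(expr, bin = cut(v, breaks = c(-Inf, 1, 10, 100, Inf),
                         labels = c("non", "low", "middle", "high"),
                         right = TRUE, ordered_result = TRUE))
}

#' Methylation profiles by expression bin and rank correlation
#'
#' Joins per-gene expression with per-gene region methylation levels and
#' reports (a) the mean methylation level per expression bin, region and
#' context, and (b) the gene-wise Spearman rank correlation between
#' expression and region methylation level, per region and context. A
#' constant methylation vector leaves the correlation undefined; such rows
#' carry `rho = NA` and are flagged.
#'
#' @param expr Tibble with gene_id and an expression column (see `value`).
#' @param region_levels Per-gene region methylation levels, as returned by
#'   [methylation_levels()] with `scope = "gene_region"` (gene_id, region,
#'   context, level).
#' @param value Name of the expression column (default `"fpkm"`).
#' @return A `meth_by_bin` list with tibbles `profile` (bin x region x
#'   context mean levels) and `correlation` (region, context, rho, p, n,
#'   defined).
#' @export
methylation_by_bin <- function(expr, region_levels, value = "fpkm") {
  check_cols(region_levels, c("gene_id", "region", "context", "level"),
             "region level table")
  binned <- bin_expression(expr, value = value)
  joined <- inner_join(select(binned, "gene_id", "bin",
                              expr_value = dplyr::all_of(value)),
                       region_levels, by = "gene_id")
  if (dplyr::n_distinct(joined$bin) < 2) {
    warn("Fewer than two expression bins are populated.")
  }
  profile <- joined |>
    group_by(.data$bin, .data$region, .data$context) |>
    summarise(mean_level = mean(.data$level), n_genes = n(),
              .groups = "drop")
  correlation <- joined |>
    group_by(.data$region, .data$context) |>
    summarise(
      n = n(),
      defined = dplyr::n_distinct(.data$level) > 1 &&
        dplyr::n_distinct(.data$expr_value) > 1,
      rho = if (defined) {
        suppressWarnings(cor.test(.data$expr_value, .data$level,
                                  method = "spearman",
                                  exact = FALSE)$estimate[[1]])
      } else NA_real_,
      p = if (defined) {
        suppressWarnings(cor.test(.data$expr_value, .data$level,
                                  method = "spearman",
                                  exact = FALSE)$p.value)
      } else NA_real_,
      .groups = "drop")
  structure(list(profile = profile, correlation = correlation),
            class = "meth_by_bin")
}

#' @export
print.meth_by_bin <- function(x, ...) {
  cat("<meth_by_bin>\n")
  print(x$correlation)
  invisible(x)
}

#' Intersect DEGs with DMGs and classify E/M quadrants
#'
#' Joins differentially expressed genes with DMR-to-gene associations and
#' labels each (gene, tissue, region, DMR) record with its quadrant: E+/E-
#' is the expression direction (up/down), M+/M- the methylation direction
#' (hyper/hypo). Genes that are DE-only or DM-only are excluded. A gene
#' with several DMRs of opposite direction within one region yields one
#' record per DMR, flagged `multi_hit`; the region-level direction
#' (`region_direction`) is the sign of the site-count-weighted mean delta
#' over the region's DMRs.
#'
#' @param degs A `deg_calls` tibble (gene_id, status, optional tissue).
#' @param dmgs DMR-gene associations from [annotate_dmr_genes()] (gene_id,
#'   region, context, delta, q, status, n_sites).
#' @return An `integration_records` tibble: gene_id, (tissue), region,
#'   context, deg_status, dmg_status, quadrant, delta, q, multi_hit,
#'   region_direction.
#' @export
common_genes <- function(degs, dmgs) {
  degs <- as_tibble(degs)
  dmgs <- as_tibble(dmgs)
  check_cols(degs, c("gene_id", "status"), "DEG table")
  check_cols(dmgs, c("gene_id", "region", "status", "delta"), "DMG table")
  de <- degs |>
    filter(.data$status %in% c("up", "down")) |>
    select("gene_id", dplyr::any_of("tissue"), deg_status = "status")
  dm <- dmgs |>
    filter(.data$status %in% c("hyper", "hypo")) |>
    rename(dmg_status = "status")
  if (!"n_sites" %in% names(dm)) dm$n_sites <- 1L
  dm <- dm |>
    group_by(.data$gene_id, .data$region) |>
    mutate(
      multi_hit = dplyr::n_distinct(.data$dmg_status) > 1,
      region_direction = if_else(
        sum(.data$delta * .data$n_sites) >= 0, "hyper", "hypo")) |>
    ungroup()
  out <- inner_join(de, dm, by = "gene_id",
                    relationship = "many-to-many") |>
    mutate(quadrant = paste0(
      if_else(.data$deg_status == "up", "E+", "E-"),
      if_else(.data$dmg_status == "hyper", "M+", "M-"))) |>
    select("gene_id", dplyr::any_of("tissue"), "region", "context",
           "deg_status", "dmg_status", "quadrant", "delta", "q",
           "multi_hit", "region_direction") |>
    arrange(.data$gene_id, .data$region)
  structure(out, class = c("integration_records", class(out)))
}

#' @export
glance.integration_records <- function(x, ...) {
  tibble(
    n_records = nrow(x),
    n_genes = dplyr::n_distinct(x$gene_id),
    n_epmp = sum(x$quadrant == "E+M+"),
    n_epmm = sum(x$quadrant == "E+M-"),
    n_emmp = sum(x$quadrant == "E-M+"),
    n_emmm = sum(x$quadrant == "E-M-"),
    n_multi_hit = sum(x$multi_hit))
}
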