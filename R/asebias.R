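#' Aggregate allele-informative read counts per gene and replicate
#'
#' Sums per-SNP paternal/maternal read depths over each gene's diagnostic
#' SNPs, per replicate. Rows already carrying a gene_id are used as-is;
#' otherwise the table is joined to the diagnostic-SNP table by (chrom, pos).
#' Rows matching no diagnostic site are skipped and tallied; genes without
#' any diagnostic SNP are absent from the output.
#'
#' @param snp_depths Tibble with chrom, pos, replicate, pat_count, mat_count
#'   and optionally gene_id.
#' @param diagnostics Optional tibble of gene-assigned diagnostic SNPs
#'   (chrom, pos, gene_id), e.g. from [assign_to_genes()]; required when
#'   `snp_depths` has no gene_id column.
#' @return A tibble with gene_id, replicate, pat_count, mat_count and a
#'   `join_tally` attribute.
#' @export
count_alleles <- function(snp_depths, diagnostics = NULL) {
  check_cols(snp_depths, c("chrom", "pos", "replicate", "pat_count",
                           "mat_count"), "allele-depth table")
  n_in <- nrow(snp_depths)
  if (!"gene_id" %in% names(snp_depths) || all(is.na(snp_depths$gene_id))) {
    if (is.null(diagnostics)) {
      abort("`snp_depths` has no gene_id column; supply `diagnostics`.")
    }
    check_cols(diagnostics, c("chrom", "pos", "gene_id"), "diagnostic table")
    snp_depths <- snp_depths |>
      select(-dplyr::any_of("gene_id")) |>
      inner_join(distinct(diagnostics, .data$chrom, .data$pos, .data$gene_id),
                 by = c("chrom", "pos"), relationship = "many-to-many")
  }
  snp_depths <- filter(snp_depths, !is.na(.data$gene_id))
  out <- snp_depths |>
    group_by(.data$gene_id, .data$replicate) |>
    summarise(pat_count = sum(.data$pat_count),
              mat_count = sum(.data$mat_count), .groups = "drop") |>
    arrange(.data$gene_id, .data$replicate)
  attr(out, "join_tally") <- c(n_input_rows = n_in,
                               n_unmatched_rows = n_in - nrow(snp_depths))
  out
}

#' Test and classify homoeolog expression bias per gene
#'
#' For each gene and replicate, tests the paternal read count against the
#' replicate total with a two-sided exact binomial test at success
#' probability 0.5, then adjusts p across genes within each replicate
#' (Benjamini-Hochberg). A gene is called paternal-biased when every
#' replicate has paternal:maternal ratio >= `ratio_hi` and q <= `alpha_q`,
#' maternal-biased when every replicate has ratio <= `ratio_lo` and
#' q <= `alpha_q`, and unbiased otherwise. A zero maternal count gives an
#' infinite ratio (which satisfies the paternal gate); no pseudocounts are
#' added. Genes with any replicate total below `min_total` are never
#' classified and carry a low-coverage flag. `mode = "pooled"` instead sums
#' counts across replicates and applies the same gates to the single pooled
#' test.
#'
#' @param allele_counts Tibble from [count_alleles()] (gene_id, replicate,
#'   pat_count, mat_count).
#' @param min_total Minimum informative reads per replicate for a gene to be
#'   classifiable (default 10).
#' @param alpha_q Significance level on the BH-adjusted p (default 0.01).
#' @param ratio_hi,ratio_lo Paternal / maternal ratio gates (defaults 2 and
#'   0.5).
#' @param mode `"per_replicate"` (default: every replicate must satisfy the
#'   gates) or `"pooled"`.
#' @return An `ase_bias_calls` tibble: gene_id, n_replicates, pat_total,
#'   mat_total, ratio (pooled), classification, low_coverage. Per-replicate
#'   statistics are available via [generics::tidy()].
#' @export
test_bias <- function(allele_counts, min_total = 10, alpha_q = 0.01,
                      ratio_hi = 2, ratio_lo = 0.5,
                      mode = c("per_replicate", "pooled")) {
  mode <- match.arg(mode)
  check_cols(allele_counts, c("gene_id", "replicate", "pat_count",
                              "mat_count"), "allele-count table")
  if (!nrow(allele_counts)) {
    out <- tibble(gene_id = character(), n_replicates = integer(),
                  pat_total = integer(), mat_total = integer(),
                  ratio = numeric(), classification = character(),
                  low_coverage = logical())
    return(new_ase_bias_calls(out, tibble(), min_total, alpha_q,
                              ratio_hi, ratio_lo, mode))
  }
  # genes absent from a replicate get explicit zero counts
  counts <- allele_counts |>
    tidyr::complete(.data$gene_id, .data$replicate,
                    fill = list(pat_count = 0L, mat_count = 0L)) |>
    mutate(total = .data$pat_count + .data$mat_count,
           ratio = .data$pat_count / .data$mat_count)

  binom_p <- function(k, n) {
    if (n == 0) return(1)
    binom.test(k, n, p = 0.5, alternative = "two.sided")$p.value
  }

  if (mode == "per_replicate") {
    per_rep <- counts |>
      mutate(p = purrr::map2_dbl(.data$pat_count, .data$total, binom_p)) |>
      group_by(.data$replicate) |>
      mutate(q = p.adjust(.data$p, method = "BH")) |>
      ungroup()
    calls <- per_rep |>
      group_by(.data$gene_id) |>
      summarise(
        n_replicates = n(),
        pat_total = sum(.data$pat_count),
        mat_total = sum(.data$mat_count),
        low_coverage = any(.data$total < min_total),
        all_pat = all(.data$ratio >= ratio_hi & .data$q <= alpha_q),
        all_mat = all(.data$ratio <= ratio_lo & .data$q <= alpha_q),
        .groups = "drop")
  } else {
    pooled <- counts |>
      group_by(.data$gene_id) |>
      summarise(n_replicates = n(),
                pat_total = sum(.data$pat_count),
                mat_total = sum(.data$mat_count),
                low_total = any(.data$total < min_total),
                .groups = "drop") |>
      mutate(ratio = .data$pat_total / .data$mat_total,
             p = purrr::map2_dbl(.data$pat_total,
                                 .data$pat_total + .data$mat_total, binom_p),
             q = p.adjust(.data$p, method = "BH"))
    per_rep <- pooled |>
      mutate(replicate = "pooled", pat_count = .data$pat_total,
             mat_count = .data$mat_total,
             total = .data$pat_total + .data$mat_total) |>
      select("gene_id", "replicate", "pat_count", "mat_count", "total",
             "ratio", "p", "q")
    calls <- pooled |>
      mutate(low_coverage = .data$low_total,
             all_pat = .data$ratio >= ratio_hi & .data$q <= alpha_q,
             all_mat = .data$ratio <= ratio_lo & .data$q <= alpha_q) |>
      select("gene_id", "n_replicates", "pat_total", "mat_total",
             "low_coverage", "all_pat", "all_mat")
  }

  out <- calls |>
    mutate(
      ratio = .data$pat_total / .data$mat_total,
      classification = dplyr::case_when(
        low_coverage ~ "unbiased",
        all_pat ~ "paternal",
        all_mat ~ "maternal",
        .default = "unbiased")) |>
    select("gene_id", "n_replicates", "pat_total", "mat_total", "ratio",
           "classification", "low_coverage") |>
    arrange(.data$gene_id)
  new_ase_bias_calls(out, per_rep, min_total, alpha_q, ratio_hi, ratio_lo,
                     mode)
}

new_ase_bias_calls <- function(calls, per_rep, min_total, alpha_q, ratio_hi,
                               ratio_lo, mode) {
  structure(calls,
            replicates = per_rep,
            params = list(min_total = min_total, alpha_q = alpha_q,
                          ratio_hi = ratio_hi, ratio_lo = ratio_lo,
                          mode = mode),
            class = c("ase_bias_calls", class(calls)))
}

#' @export
tidy.ase_bias_calls <- function(x, ...) {
  as_tibble(attr(x, "replicates"))
}

#' @export
glance.ase_bias_calls <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_paternal = sum(x$classification == "paternal"),
    n_maternal = sum(x$classification == "maternal"),
    n_unbiased = sum(x$classification == "unbiased"),
    n_low_coverage = sum(x$low_coverage),
    mode = attr(x, "params")$mode)
}

#' Summarise subgenome dominance across the two reference alignments
#'
#' Combines per-reference bias calls (optionally split by tissue) with DEG
#' direction tables to count bias DEGs per tissue, compare the expression
#' level of the paternal- versus maternal-biased sets, and co-locate shared
#' bias DEGs across references through the ortholog map, partitioning them
#' into consistently up-regulated, consistently down-regulated and
#' mixed-direction genes (the partition sums to the shared total).
#'
#' @param bias_a,bias_b Bias-call tibbles for the two references (gene_id,
#'   classification, optional tissue column; e.g. row-bound per-tissue
#'   results of [test_bias()]).
#' @param deg_a,deg_b Optional DEG tables (gene_id, status, optional tissue)
#'   used to restrict to bias DEGs and to direction the shared partition.
#' @param orthologs Optional ortholog map (paternal_gene, maternal_gene)
#'   used to co-locate genes across references; reference-B gene ids are
#'   translated to reference-A ids. Genes without a mapping are tallied as
#'   reference-unique.
#' @param fpkm_a,fpkm_b Optional expression tables (gene_id, fpkm, optional
#'   tissue) for the expression-level comparison.
#' @param reference_names Length-2 labels for the two reference alignments.
#' @return A `dominance_summary` list: `per_tissue` counts, `expression`
#'   comparison (NA and flagged undefined when a bias set is empty),
#'   `totals` integrated over references, `shared_partition`
#'   (up/down/mixed/total) and the underlying `shared_genes` table.
#' @export
dominance_summary <- function(bias_a, bias_b, deg_a = NULL, deg_b = NULL,
                              orthologs = NULL, fpkm_a = NULL, fpkm_b = NULL,
                              reference_names = c("paternal_ref",
                                                  "maternal_ref")) {
  prep <- function(bias, deg, fpkm, ref) {
    b <- as_tibble(bias)
    if (!"tissue" %in% names(b)) b$tissue <- "all"
    b <- b |>
      filter(.data$classification %in% c("paternal", "maternal")) |>
      select("gene_id", "tissue", "classification")
    if (!is.null(deg)) {
      d <- as_tibble(deg)
      if (!"tissue" %in% names(d)) d$tissue <- "all"
      b <- b |>
        inner_join(select(d, "gene_id", "tissue", "status"),
                   by = c("gene_id", "tissue")) |>
        filter(.data$status %in% c("up", "down"))
    } else {
      b$status <- NA_character_
    }
    if (!is.null(fpkm)) {
      f <- as_tibble(fpkm)
      if (!"tissue" %in% names(f)) f$tissue <- "all"
      f <- f |>
        group_by(.data$gene_id, .data$tissue) |>
        summarise(fpkm = mean(.data$fpkm), .groups = "drop")
      b <- left_join(b, f, by = c("gene_id", "tissue"))
    } else {
      b$fpkm <- NA_real_
    }
    mutate(b, reference = ref)
  }

  a <- prep(bias_a, deg_a, fpkm_a, reference_names[1])
  b <- prep(bias_b, deg_b, fpkm_b, reference_names[2])
  both <- bind_rows(a, b)

  per_tissue <- both |>
    count(.data$reference, .data$tissue, .data$classification) |>
    tidyr::pivot_wider(names_from = "classification", values_from = "n",
                       values_fill = 0L) |>
    (\(d) {
      for (cl in c("paternal", "maternal")) if (!cl %in% names(d)) d[[cl]] <- 0L
      d
    })() |>
    rename(n_paternal_bias = "paternal", n_maternal_bias = "maternal")

  expression <- both |>
    group_by(.data$reference, .data$classification) |>
    summarise(mean_fpkm = mean(.data$fpkm, na.rm = TRUE),
              n = n(), .groups = "drop") |>
    tidyr::complete(reference = reference_names,
                    classification = c("paternal", "maternal"),
                    fill = list(n = 0L)) |>
    mutate(mean_fpkm = if_else(.data$n == 0L, NA_real_, .data$mean_fpkm),
           defined = .data$n > 0L)

  # co-location across references: translate reference-B ids to reference-A
  n_unmapped <- 0L
  b_mapped <- b
  if (!is.null(orthologs) && nrow(b)) {
    om <- distinct(as_tibble(orthologs), .data$paternal_gene,
                   .data$maternal_gene)
    b_mapped <- b |>
      left_join(om, by = c(gene_id = "maternal_gene"))
    n_unmapped <- sum(is.na(b_mapped$paternal_gene))
    b_mapped <- b_mapped |>
      filter(!is.na(.data$paternal_gene)) |>
      mutate(gene_id = .data$paternal_gene) |>
      select(-"paternal_gene")
  }
  joint <- bind_rows(a, b_mapped)
  totals <- joint |>
    distinct(.data$gene_id, .data$classification) |>
    count(.data$classification) |>
    tidyr::complete(classification = c("paternal", "maternal"),
                    fill = list(n = 0L))

  shared_ids <- intersect(unique(a$gene_id), unique(b_mapped$gene_id))
  shared_genes <- joint |>
    filter(.data$gene_id %in% shared_ids) |>
    group_by(.data$gene_id) |>
    summarise(
      direction = if (all(is.na(.data$status))) NA_character_
        else if (all(.data$status == "up", na.rm = TRUE)) "up"
        else if (all(.data$status == "down", na.rm = TRUE)) "down"
        else "mixed",
      .groups = "drop")
  shared_partition <- tibble(
    up = sum(shared_genes$direction == "up", na.rm = TRUE),
    down = sum(shared_genes$direction == "down", na.rm = TRUE),
    mixed = sum(shared_genes$direction == "mixed", na.rm = TRUE),
    total = length(shared_ids))

  structure(
    list(per_tissue = per_tissue, expression = expression,
         totals = totals, shared_partition = shared_partition,
         shared_genes = shared_genes, n_unmapped = n_unmapped,
         reference_names = reference_names),
    class = "dominance_summary")
}

#' @export
print.dominance_summary <- function(x, ...) {
  cat("<dominance_summary>\n")
  cat("  integrated bias genes:",
      paste(sprintf("%s=%d", x$totals$classification, x$totals$n),
            collapse = ", "), "\n")
  sp <- x$shared_partition
  cat(sprintf("  shared across references: %d (up %d / down %d / mixed %d)\n",
              sp$total, sp$up, sp$down, sp$mixed))
  if (x$n_unmapped > 0) {
    cat("  reference-unique (no ortholog):", x$n_unmapped, "\n")
  }
  invisible(x)
}

#' @export
glance.dominance_summary <- function(x, ...) {
  tibble(
    total_paternal_bias = x$totals$n[x$totals$classification == "paternal"],
    total_maternal_bias = x$totals$n[x$totals$classification == "maternal"],
    shared = x$shared_partition$total,
    shared_up = x$shared_partition$up,
    shared_down = x$shared_partition$down,
    shared_mixed = x$shared_partition$mixed,
    n_unmapped = x$n_unmapped)
}
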