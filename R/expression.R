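#' Compute FPKM from raw counts
#'
#' Applies the FPKM identity fpkm = count * 1e9 / (gene_length *
#' library_size) to a wide count matrix (one gene_id column plus one column
#' per sample). Library sizes default to the per-sample column totals.
#'
#' @param counts Tibble with a gene_id column and one numeric column per
#'   sample.
#' @param gene_lengths Tibble (gene_id, length) or named numeric vector of
#'   transcript lengths in bp.
#' @param library_sizes Optional named numeric vector of total mapped
#'   fragments per sample; defaults to column sums of `counts`.
#' @return A long tibble: gene_id, sample, count, gene_length,
#'   library_size, fpkm.
#' @export
compute_fpkm <- function(counts, gene_lengths, library_sizes = NULL) {
  check_cols(counts, "gene_id", "count table")
  if (is.numeric(gene_lengths) && !is.null(names(gene_lengths))) {
    gene_lengths <- tibble(gene_id = names(gene_lengths),
                           length = unname(gene_lengths))
  }
  check_cols(gene_lengths, c("gene_id", "length"), "gene length table")
  if (any(gene_lengths$length <= 0)) {
    abort("All gene lengths must be positive.",
          class = "hybridscope_config_error")
  }
  samples <- setdiff(names(counts), "gene_id")
  if (is.null(library_sizes)) {
    library_sizes <- vapply(counts[samples], sum, numeric(1))
  }
  if (any(library_sizes <= 0)) {
    abort("All library sizes must be positive.",
          class = "hybridscope_config_error")
  }
  counts |>
    tidyr::pivot_longer(cols = dplyr::all_of(samples), names_to = "sample",
                        values_to = "count") |>
    inner_join(gene_lengths, by = "gene_id") |>
    rename(gene_length = "length") |>
    mutate(library_size = unname(library_sizes[.data$sample]),
           fpkm = .data$count * 1e9 /
             (.data$gene_length * .data$library_size)) |>
    arrange(.data$gene_id, .data$sample)
}

#' Call differentially expressed genes between hybrid and maternal groups
#'
#' Fits the count matrix with DESeq2 (Wald test on the hybrid-vs-maternal
#' contrast, median-of-ratios normalisation) and classifies each gene with
#' the thresholds adjusted p < `alpha` and |log2 fold change| >= `lfc_min`.
#' The fold-change sign convention is hybrid over maternal. With a single
#' replicate per group, where dispersion cannot be estimated, a
#' library-size-conditioned exact binomial test is used instead (method
#' `"exact"`, chosen automatically). Genes with all-zero counts are `ns`
#' and flagged. Externally computed tables can be classified with
#' [deg_calls_from_table()].
#'
#' @param counts Tibble with gene_id plus one column of raw counts per
#'   sample.
#' @param groups Named character vector mapping sample column names to
#'   `"hybrid"` or `"maternal"`.
#' @param tissue Optional tissue label attached to the output.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param lfc_min Minimum absolute log2 fold change (default 1).
#' @param method `"deseq2"` (default with replication) or `"exact"`.
#' @return A `deg_calls` tibble: gene_id, (tissue), base_mean, log2fc,
#'   pvalue, padj, status (up/down/ns), zero_expression.
#' @export
call_degs <- function(counts, groups, tissue = NULL, alpha = 0.05,
                      lfc_min = 1, method = c("deseq2", "exact")) {
  method <- match.arg(method)
  check_cols(counts, "gene_id", "count table")
  samples <- setdiff(names(counts), "gene_id")
  missing <- setdiff(samples, names(groups))
  if (length(missing)) {
    abort(sprintf("`groups` lacks sample(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "hybridscope_config_error")
  }
  groups <- groups[samples]
  if (!all(groups %in% c("hybrid", "maternal"))) {
    abort("`groups` values must be \"hybrid\" or \"maternal\".",
          class = "hybridscope_config_error")
  }
  if (min(table(factor(groups, c("hybrid", "maternal")))) < 1) {
    abort("Both groups need at least one sample.",
          class = "hybridscope_config_error")
  }
  if (method == "deseq2" && min(table(groups)) < 2) method <- "exact"

  mat <- as.matrix(counts[samples])
  storage.mode(mat) <- "integer"
  rownames(mat) <- counts$gene_id
  zero <- rowSums(mat) == 0

  if (method == "deseq2") {
    dds <- DESeq2::DESeqDataSetFromMatrix(
      countData = mat,
      colData = S4Vectors::DataFrame(
        group = factor(groups, levels = c("maternal", "hybrid"))),
      design = ~group)
    # parametric dispersion fit can fail on small or homogeneous panels;
    # fall back to gene-wise estimates
    dds <- tryCatch(
      DESeq2::DESeq(dds, quiet = TRUE),
      error = function(e) {
        dds <- DESeq2::estimateSizeFactors(dds)
        dds <- DESeq2::estimateDispersionsGeneEst(dds)
        DESeq2::dispersions(dds) <- S4Vectors::mcols(dds)$dispGeneEst
        DESeq2::nbinomWaldTest(dds)
      })
    res <- DESeq2::results(dds, contrast = c("group", "hybrid", "maternal"))
    out <- tibble(gene_id = rownames(res),
                  base_mean = res$baseMean,
                  log2fc = res$log2FoldChange,
                  pvalue = res$pvalue,
                  padj = res$padj)
  } else {
    h <- which(groups == "hybrid")
    m <- which(groups == "maternal")
    size_h <- sum(mat[, h])
    size_m <- sum(mat[, m])
    a <- rowSums(mat[, h, drop = FALSE])
    b <- rowSums(mat[, m, drop = FALSE])
    p_h <- size_h / (size_h + size_m)
    pv <- vapply(seq_along(a), function(i) {
      n <- a[i] + b[i]
      if (n == 0) return(NA_real_)
      binom.test(a[i], n, p = p_h, alternative = "two.sided")$p.value
    }, numeric(1))
    out <- tibble(
      gene_id = counts$gene_id,
      base_mean = (a / length(h) + b / length(m)) / 2,
      log2fc = log2((a / size_h + 0.5 / size_h) /
                      (b / size_m + 0.5 / size_m)),
      pvalue = pv,
      padj = p.adjust(pv, method = "BH"))
  }

  out <- out |>
    mutate(zero_expression = unname(zero[.data$gene_id]),
           status = dplyr::case_when(
             is.na(.data$padj) | .data$zero_expression ~ "ns",
             .data$padj < alpha & .data$log2fc >= lfc_min ~ "up",
             .data$padj < alpha & .data$log2fc <= -lfc_min ~ "down",
             .default = "ns"))
  if (!is.null(tissue)) out <- mutate(out, tissue = tissue, .after = "gene_id")
  structure(out,
            params = list(alpha = alpha, lfc_min = lfc_min, method = method),
            class = c("deg_calls", class(out)))
}

#' Classify an externally computed differential-expression table
#'
#' Applies the up/down/ns status rule (padj < `alpha`,
#' |log2fc| >= `lfc_min`) to a table of per-gene log2 fold changes and
#' adjusted p-values produced by any differential-expression tool, so
#' external results slot into the downstream accounting unchanged.
#'
#' @param df Tibble with gene_id, log2fc and padj (optionally tissue).
#' @inheritParams call_degs
#' @return A `deg_calls` tibble.
#' @export
deg_calls_from_table <- function(df, alpha = 0.05, lfc_min = 1) {
  check_cols(df, c("gene_id", "log2fc", "padj"), "DEG table")
  out <- df |>
    mutate(status = dplyr::case_when(
      is.na(.data$padj) ~ "ns",
      .data$padj < alpha & .data$log2fc >= lfc_min ~ "up",
      .data$padj < alpha & .data$log2fc <= -lfc_min ~ "down",
      .default = "ns"))
  structure(out,
            params = list(alpha = alpha, lfc_min = lfc_min,
                          method = "external"),
            class = c("deg_calls", class(out)))
}

#' @export
glance.deg_calls <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_up = sum(x$status == "up"),
         n_down = sum(x$status == "down"),
         n_ns = sum(x$status == "ns"),
         method = attr(x, "params")$method)
}

#' Partition genes shared as DEGs across tissues
#'
#' A gene is shared when it is differentially expressed (status up or down)
#' in every tissue present in the input. Shared genes are partitioned into
#' uniformly up-regulated, uniformly down-regulated, and
#' direction-inconsistent sets; the three categories are disjoint and sum
#' to the shared total. Pairwise tissue overlap counts are reported
#' alongside.
#'
#' @param degs A tibble with gene_id, tissue and status columns (row-bind
#'   per-tissue [call_degs()] results), or a named list of per-tissue DEG
#'   tables.
#' @return A `shared_gene_partition` list: `shared` (gene_id, category),
#'   `counts` (one-row tibble n_shared, n_all_up, n_all_down,
#'   n_inconsistent), and `pairwise` tissue-pair DEG overlaps.
#' @export
shared_gene_partition <- function(degs) {
  if (is.list(degs) && !is.data.frame(degs)) {
    degs <- bind_rows(purrr::imap(degs, function(d, nm) {
      d <- as_tibble(d)
      if (!"tissue" %in% names(d)) d$tissue <- nm
      d
    }))
  }
  check_cols(degs, c("gene_id", "tissue", "status"), "DEG table")
  tissues <- unique(degs$tissue)
  de <- degs |> filter(.data$status %in% c("up", "down"))
  shared <- de |>
    distinct(.data$gene_id, .data$tissue, .data$status) |>
    group_by(.data$gene_id) |>
    summarise(n_tissues = dplyr::n_distinct(.data$tissue),
              category = if (all(.data$status == "up")) "all_up"
                else if (all(.data$status == "down")) "all_down"
                else "inconsistent",
              .groups = "drop") |>
    filter(.data$n_tissues == length(tissues)) |>
    select("gene_id", "category")
  counts <- tibble(
    n_shared = nrow(shared),
    n_all_up = sum(shared$category == "all_up"),
    n_all_down = sum(shared$category == "all_down"),
    n_inconsistent = sum(shared$category == "inconsistent"))
  pairwise <- NULL
  if (length(tissues) > 1) {
    pairs <- utils::combn(sort(tissues), 2, simplify = FALSE)
    pairwise <- purrr::map_dfr(pairs, function(pr) {
      g1 <- unique(de$gene_id[de$tissue == pr[1]])
      g2 <- unique(de$gene_id[de$tissue == pr[2]])
      tibble(tissue_1 = pr[1], tissue_2 = pr[2],
             n_overlap = length(intersect(g1, g2)))
    })
  }
  structure(list(shared = shared, counts = counts, pairwise = pairwise,
                 tissues = tissues),
            class = "shared_gene_partition")
}

#' @export
print.shared_gene_partition <- function(x, ...) {
  cat("<shared_gene_partition>", length(x$tissues), "tissues\n")
  print(x$counts)
  invisible(x)
}

#' Overlap DEG sets called against the two parental references
#'
#' Joins the two gene universes through the ortholog map and splits the
#' differentially expressed genes into the overlap (DE against both
#' references), the paternal-unique and the maternal-unique sets. The three
#' sets are disjoint; overlap + unique equals each reference's total.
#' Maternal-reference genes without an ortholog cannot overlap and are
#' counted maternal-unique.
#'
#' @param deg_paternal,deg_maternal DEG tables (rows with status up/down
#'   are used) or plain character vectors of DE gene ids.
#' @param orthologs Ortholog map tibble (paternal_gene, maternal_gene).
#' @return A `reference_venn` list with `counts` (n_overlap,
#'   n_unique_paternal, n_unique_maternal) and the member sets.
#' @export
reference_venn <- function(deg_paternal, deg_maternal, orthologs) {
  as_set <- function(x) {
    if (is.character(x)) return(unique(x))
    check_cols(x, c("gene_id", "status"), "DEG table")
    unique(x$gene_id[x$status %in% c("up", "down")])
  }
  pat <- as_set(deg_paternal)
  mat <- as_set(deg_maternal)
  om <- distinct(as_tibble(orthologs), .data$paternal_gene,
                 .data$maternal_gene)
  pat_de_pairs <- om |> filter(.data$paternal_gene %in% pat)
  overlap_pairs <- pat_de_pairs |> filter(.data$maternal_gene %in% mat)
  overlap_pat <- unique(overlap_pairs$paternal_gene)
  overlap_mat <- unique(overlap_pairs$maternal_gene)
  structure(
    list(counts = tibble(
           n_overlap = length(overlap_pat),
           n_unique_paternal = length(setdiff(pat, overlap_pat)),
           n_unique_maternal = length(setdiff(mat, overlap_mat))),
         overlap = overlap_pairs,
         unique_paternal = setdiff(pat, overlap_pat),
         unique_maternal = setdiff(mat, overlap_mat)),
    class = "reference_venn")
}

#' @export
print.reference_venn <- function(x, ...) {
  cat("<reference_venn>\n")
  print(x$counts)
  invisible(x)
}
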