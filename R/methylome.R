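#' Read a cytosine-report methylation table
#'
#' Reads a per-cytosine count table (chrom, pos, strand, context,
#' count_m, count_u), the layout written by bisulfite pipelines' cytosine
#' reports. A header line is detected; otherwise the canonical column order
#' is assumed.
#'
#' @param path Path to a TSV file (plain or gzipped).
#' @return A tibble of methylation sites.
#' @export
read_cx_report <- function(path) {
  if (!file.exists(path)) abort(sprintf("Cytosine report not found: %s", path))
  cols <- c("chrom", "pos", "strand", "context", "count_m", "count_u")
  first <- readLines(path, n = 1)
  if (grepl("chrom", first, fixed = TRUE)) {
    out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    out <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                           progress = FALSE)
  }
  check_cols(out, cols, "cytosine report")
  bad <- setdiff(unique(out$context), c("CG", "CHG", "CHH"))
  if (length(bad)) {
    abort(sprintf("Unknown methylation context(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  out
}

#' Call methylated cytosines against the bisulfite conversion error
#'
#' Tests each covered site one-sided for more methylated reads than the
#' non-conversion error rate explains: p = P(X >= count_m) with
#' X ~ Binomial(coverage, conversion_error), BH-adjusted across all
#' evaluated sites. A site is methylated when q <= `alpha_q`. Sites with
#' zero coverage are flagged unevaluated (NA p and q).
#'
#' @param sites Methylation site tibble (chrom, pos, strand, context,
#'   count_m, count_u).
#' @param conversion_error Bisulfite non-conversion rate in (0, 1).
#' @param alpha_q Significance level on q (default 0.05).
#' @return `sites` with coverage, level, p, q, evaluated and methylated
#'   columns.
#' @export
call_methylcytosines <- function(sites, conversion_error = 0.01,
                                 alpha_q = 0.05) {
  if (!is.numeric(conversion_error) || conversion_error <= 0 ||
      conversion_error >= 1) {
    abort("`conversion_error` must lie strictly between 0 and 1.",
          class = "hybridscope_config_error")
  }
  check_cols(sites, c("count_m", "count_u"), "site table")
  out <- sites |>
    mutate(coverage = .data$count_m + .data$count_u,
           level = if_else(.data$coverage > 0,
                           .data$count_m / .data$coverage, NA_real_),
           evaluated = .data$coverage > 0,
           p = if_else(.data$evaluated,
                       stats::pbinom(.data$count_m - 1L, .data$coverage,
                                     conversion_error, lower.tail = FALSE),
                       NA_real_))
  q <- rep(NA_real_, nrow(out))
  q[out$evaluated] <- p.adjust(out$p[out$evaluated], method = "BH")
  out$q <- q
  out$methylated <- !is.na(out$q) & out$q <= alpha_q
  out
}

#' Pooled methylation levels by scope
#'
#' Computes coverage-weighted methylation levels, sum(count_m) /
#' sum(count_m + count_u), per cytosine context (plus the pooled `allC`),
#' genome-wide, per chromosome, or per gene region (gene body and
#' strand-aware 2 kb flanks). Scopes with no covered site yield no row
#' rather than a zero level.
#'
#' @param sites Methylation site tibble.
#' @param gene_models Required for `scope = "gene_region"`: a `gene_models`
#'   object, GFF3 path or `hybrid_cross_sim`.
#' @param scope One of `"genome"`, `"chromosome"`, `"gene_region"`.
#' @param flank Flank width for gene regions (default 2000).
#' @return A tibble with the scope columns, context, n_sites, total_m,
#'   total_cov and level.
#' @export
methylation_levels <- function(sites, gene_models = NULL,
                               scope = c("genome", "chromosome",
                                         "gene_region"),
                               flank = 2000L) {
  scope <- match.arg(scope)
  check_cols(sites, c("chrom", "pos", "context", "count_m", "count_u"),
             "site table")
  sites <- filter(sites, .data$count_m + .data$count_u > 0)
  pool <- function(df, ...) {
    ctx <- df |>
      group_by(..., .data$context) |>
      summarise(n_sites = n(), total_m = sum(.data$count_m),
                total_cov = sum(.data$count_m + .data$count_u),
                .groups = "drop")
    allc <- df |>
      group_by(...) |>
      summarise(n_sites = n(), total_m = sum(.data$count_m),
                total_cov = sum(.data$count_m + .data$count_u),
                .groups = "drop") |>
      mutate(context = "allC")
    bind_rows(ctx, allc) |>
      mutate(level = .data$total_m / .data$total_cov)
  }
  if (scope == "genome") return(pool(sites))
  if (scope == "chromosome") return(pool(sites, .data$chrom) |>
                                      arrange(.data$chrom, .data$context))
  if (is.null(gene_models)) {
    abort("`gene_models` is required for scope = \"gene_region\".")
  }
  regions <- gene_regions(gene_models, flank = flank)
  site_gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos, width = 1L))
  reg_gr <- tbl_to_granges(regions)
  hits <- GenomicRanges::findOverlaps(site_gr, reg_gr, ignore.strand = TRUE)
  joined <- sites[S4Vectors::queryHits(hits), ] |>
    mutate(gene_id = regions$gene_id[S4Vectors::subjectHits(hits)],
           region = regions$region[S4Vectors::subjectHits(hits)])
  pool(joined, .data$gene_id, .data$region) |>
    arrange(.data$gene_id, .data$region, .data$context)
}

#' Per-context DMR eligibility criteria
#'
#' The window criteria used by [call_dmrs()]: a window is eligible when it
#' holds at least `min_sites` cytosines of the tested context, and a call
#' additionally requires the absolute pooled level difference to reach
#' `min_delta` (CG/CHG: 5 sites, 0.25; CHH: 15 sites, 0.15; pooled allC:
#' 20 sites, 0.2) at q <= 0.05.
#'
#' @return A tibble with context, min_sites and min_delta.
#' @export
dmr_criteria <- function() {
  tibble(context = c("CG", "CHG", "CHH", "allC"),
         min_sites = c(5L, 5L, 15L, 20L),
         min_delta = c(0.25, 0.25, 0.15, 0.2))
}

# Two-sided Fisher p for pooled 2x2 count tables, deduplicated so repeated
# tables are tested once.
fisher_p_vec <- function(m_a, u_a, m_b, u_b) {
  key <- paste(m_a, u_a, m_b, u_b, sep = "_")
  uk <- !duplicated(key)
  pu <- vapply(which(uk), function(i) {
    stats::fisher.test(matrix(c(m_a[i], u_a[i], m_b[i], u_b[i]), nrow = 2,
                              byrow = TRUE))$p.value
  }, numeric(1))
  unname(setNames(pu, key[uk])[key])
}

#' Call differentially methylated regions between two groups
#'
#' Tiles the genome into fixed, non-overlapping windows anchored at
#' coordinate 0, pools methylated/unmethylated counts per window, context
#' and group over sites covered by at least `min_cov` reads in both groups,
#' and tests each eligible window with a two-sided Fisher exact test on the
#' pooled 2x2 table. p-values are BH-adjusted per context across all tested
#' windows. A window is called hyper-/hypomethylated (group A relative to
#' group B) when q <= `alpha_q` and |delta| reaches the context's minimum
#' difference; windows below the context's minimum site count are reported
#' untested.
#'
#' @param sites_a,sites_b Site tibbles for the two groups, on the same
#'   coordinate system.
#' @param window Window width in bp (default 200).
#' @param min_cov Minimum per-site coverage required in both groups
#'   (default 4).
#' @param alpha_q Significance level on q (default 0.05).
#' @param criteria Eligibility table, see [dmr_criteria()].
#' @param contexts Contexts to test; `"allC"` pools all contexts.
#' @return A `dmr_calls` tibble: chrom, start, end (0-based half-open
#'   window), context, n_sites, pooled counts, level_a, level_b, delta
#'   (level_a - level_b), p, q, tested and status (hyper/hypo/none).
#' @export
call_dmrs <- function(sites_a, sites_b, window = 200L, min_cov = 4L,
                      alpha_q = 0.05, criteria = dmr_criteria(),
                      contexts = c("CG", "CHG", "CHH", "allC")) {
  assert_count(window, "window")
  joined <- join_site_groups(sites_a, sites_b, min_cov)
  joined <- joined |>
    mutate(start = ((.data$pos - 1L) %/% as.integer(window)) *
             as.integer(window))

  win_ctx <- function(df, ctx) {
    df |>
      group_by(.data$chrom, .data$start) |>
      summarise(n_sites = n(),
                m_a = sum(.data$count_m_a), u_a = sum(.data$count_u_a),
                m_b = sum(.data$count_m_b), u_b = sum(.data$count_u_b),
                .groups = "drop") |>
      mutate(context = ctx)
  }
  pieces <- list()
  for (ctx in setdiff(contexts, "allC")) {
    pieces[[ctx]] <- win_ctx(filter(joined, .data$context == ctx), ctx)
  }
  if ("allC" %in% contexts) pieces[["allC"]] <- win_ctx(joined, "allC")
  wins <- bind_rows(pieces)
  if (!nrow(wins)) {
    return(new_dmr_calls(
      tibble(chrom = character(), start = integer(), end = integer(),
             context = character(), n_sites = integer(), m_a = integer(),
             u_a = integer(), m_b = integer(), u_b = integer(),
             level_a = numeric(), level_b = numeric(), delta = numeric(),
             p = numeric(), q = numeric(), tested = logical(),
             status = character()),
      window, min_cov, alpha_q, criteria))
  }

  wins <- wins |>
    left_join(criteria, by = "context") |>
    mutate(end = .data$start + as.integer(window),
           level_a = .data$m_a / (.data$m_a + .data$u_a),
           level_b = .data$m_b / (.data$m_b + .data$u_b),
           delta = .data$level_a - .data$level_b,
           tested = .data$n_sites >= .data$min_sites)

  wins$p <- NA_real_
  idx <- which(wins$tested)
  if (length(idx)) {
    wins$p[idx] <- fisher_p_vec(wins$m_a[idx], wins$u_a[idx],
                                wins$m_b[idx], wins$u_b[idx])
  }
  wins <- wins |>
    group_by(.data$context) |>
    mutate(q = {
      qq <- rep(NA_real_, n())
      qq[.data$tested] <- p.adjust(.data$p[.data$tested], method = "BH")
      qq
    }) |>
    ungroup() |>
    mutate(status = dplyr::case_when(
      .data$tested & .data$q <= alpha_q & .data$delta >= .data$min_delta ~
        "hyper",
      .data$tested & .data$q <= alpha_q & .data$delta <= -.data$min_delta ~
        "hypo",
      .default = "none")) |>
    select("chrom", "start", "end", "context", "n_sites", "m_a", "u_a",
           "m_b", "u_b", "level_a", "level_b", "delta", "p", "q", "tested",
           "status") |>
    arrange(.data$context, .data$chrom, .data$start)
  new_dmr_calls(wins, window, min_cov, alpha_q, criteria)
}

new_dmr_calls <- function(df, window, min_cov, alpha_q, criteria) {
  structure(df,
            params = list(window = window, min_cov = min_cov,
                          alpha_q = alpha_q, criteria = criteria),
            class = c("dmr_calls", class(df)))
}

#' @export
glance.dmr_calls <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$context) |>
    summarise(n_windows = n(), n_tested = sum(.data$tested),
              n_hyper = sum(.data$status == "hyper"),
              n_hypo = sum(.data$status == "hypo"), .groups = "drop")
}

join_site_groups <- function(sites_a, sites_b, min_cov) {
  for (nm in list(sites_a, sites_b)) {
    check_cols(nm, c("chrom", "pos", "strand", "context", "count_m",
                     "count_u"), "site table")
  }
  inner_join(sites_a, sites_b,
             by = c("chrom", "pos", "strand", "context"),
             suffix = c("_a", "_b")) |>
    filter(.data$count_m_a + .data$count_u_a >= min_cov,
           .data$count_m_b + .data$count_u_b >= min_cov)
}

#' Call differentially methylated cytosines between two groups
#'
#' Site-level analogue of [call_dmrs()]: every cytosine covered by at least
#' `min_cov` reads in both groups is tested with a two-sided Fisher exact
#' test, BH-adjusted per context, and called when q <= `alpha_q` and
#' |delta| >= `min_delta`.
#'
#' @inheritParams call_dmrs
#' @param min_delta Minimum absolute level difference (default 0.25).
#' @return A tibble: chrom, pos, strand, context, counts, levels, delta, p,
#'   q, status.
#' @export
call_dmcs <- function(sites_a, sites_b, min_cov = 4L, min_delta = 0.25,
                      alpha_q = 0.05) {
  joined <- join_site_groups(sites_a, sites_b, min_cov)
  if (!nrow(joined)) {
    return(tibble(chrom = character(), pos = integer(), strand = character(),
                  context = character(), count_m_a = integer(),
                  count_u_a = integer(), count_m_b = integer(),
                  count_u_b = integer(), level_a = numeric(),
                  level_b = numeric(), delta = numeric(), p = numeric(),
                  q = numeric(), status = character()))
  }
  joined |>
    mutate(level_a = .data$count_m_a / (.data$count_m_a + .data$count_u_a),
           level_b = .data$count_m_b / (.data$count_m_b + .data$count_u_b),
           delta = .data$level_a - .data$level_b,
           p = fisher_p_vec(.data$count_m_a, .data$count_u_a,
                            .data$count_m_b, .data$count_u_b)) |>
    group_by(.data$context) |>
    mutate(q = p.adjust(.data$p, method = "BH")) |>
    ungroup() |>
    mutate(status = dplyr::case_when(
      .data$q <= alpha_q & .data$delta >= min_delta ~ "hyper",
      .data$q <= alpha_q & .data$delta <= -min_delta ~ "hypo",
      .default = "none")) |>
    arrange(.data$chrom, .data$pos, .data$context)
}

#' Associate DMRs with genes
#'
#' A gene is differentially methylated (a DMG) when at least one called DMR
#' overlaps its gene body or its strand-aware 2 kb flanks. Overlap is
#' computed on half-open windows against 1-based inclusive regions; a DMR
#' whose window touches a region by a single base is associated.
#'
#' @param dmr_calls A `dmr_calls` tibble (only rows with status other than
#'   `"none"` are associated).
#' @param gene_models A `gene_models` object, GFF3 path or
#'   `hybrid_cross_sim`.
#' @param flank Flank width in bp (default 2000).
#' @return A tibble with gene_id, region, chrom, start, end, context,
#'   delta, q and status, one row per (gene, region, DMR) association.
#' @export
annotate_dmr_genes <- function(dmr_calls, gene_models, flank = 2000L) {
  calls <- as_tibble(dmr_calls) |> filter(.data$status != "none")
  regions <- gene_regions(gene_models, flank = flank)
  if (!nrow(calls)) {
    return(tibble(gene_id = character(), region = character(),
                  chrom = character(), start = integer(), end = integer(),
                  context = character(), n_sites = integer(),
                  delta = numeric(), q = numeric(), status = character()))
  }
  # DMR windows are 0-based half-open; convert to 1-based inclusive
  dmr_gr <- GenomicRanges::GRanges(
    seqnames = calls$chrom,
    ranges = IRanges::IRanges(start = calls$start + 1L, end = calls$end))
  reg_gr <- tbl_to_granges(regions)
  hits <- GenomicRanges::findOverlaps(dmr_gr, reg_gr, ignore.strand = TRUE)
  calls[S4Vectors::queryHits(hits), ] |>
    mutate(gene_id = regions$gene_id[S4Vectors::subjectHits(hits)],
           region = regions$region[S4Vectors::subjectHits(hits)]) |>
    select("gene_id", "region", "chrom", "start", "end", "context",
           "n_sites", "delta", "q", "status") |>
    arrange(.data$gene_id, .data$region, .data$start, .data$context)
}
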