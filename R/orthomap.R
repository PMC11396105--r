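#' Read an all-vs-all similarity hit table
#'
#' Reads the standard 12-column tabular hit format (query id, subject id,
#' percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, e-value, bitscore). A header line is
#' detected and honoured; otherwise the canonical column order is assumed.
#'
#' @param path Path to a tab-separated hit table.
#' @return A tibble with at least qseqid, sseqid, evalue, bitscore.
#' @export
read_similarity_hits <- function(path) {
  if (!file.exists(path)) abort(sprintf("Hit table not found: %s", path))
  canonical <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")
  first <- readLines(path, n = 1)
  has_header <- grepl("qseqid", first, fixed = TRUE)
  if (has_header) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, col_names = canonical, show_col_types = FALSE,
                    progress = FALSE)
  }
}

best_hit_per_query <- function(hits) {
  # best = highest bitscore; ties by smallest evalue, then subject id
  hits |>
    arrange(.data$qseqid, desc(.data$bitscore), .data$evalue, .data$sseqid) |>
    group_by(.data$qseqid) |>
    slice_head(n = 1) |>
    ungroup()
}

#' Reciprocal best-hit ortholog pairing
#'
#' Pairs genes across the two parental gene sets: after removing hits with
#' `evalue > evalue_cutoff`, (a, b) is an ortholog pair iff b is a's
#' best-scoring surviving hit in the A-to-B table and a is b's best in the
#' B-to-A table. "Best" means highest bitscore, with ties broken by smallest
#' e-value and then lexicographic subject id, so the output is deterministic.
#' The result is a partial matching: no gene appears in more than one pair.
#'
#' @param hits_ab,hits_ba Hit tibbles (or paths) for the two directions.
#' @param evalue_cutoff Hits with a larger e-value are discarded first
#'   (default 1e-5).
#' @return A tibble with columns paternal_gene (query side of `hits_ab`),
#'   maternal_gene, bitscore_ab, bitscore_ba.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, evalue_cutoff = 1e-5) {
  if (is.character(hits_ab)) hits_ab <- read_similarity_hits(hits_ab)
  if (is.character(hits_ba)) hits_ba <- read_similarity_hits(hits_ba)
  if (!is.numeric(evalue_cutoff) || evalue_cutoff <= 0) {
    abort("`evalue_cutoff` must be positive.",
          class = "hybridscope_config_error")
  }
  empty <- tibble(paternal_gene = character(), maternal_gene = character(),
                  bitscore_ab = numeric(), bitscore_ba = numeric())
  if (!nrow(hits_ab) || !nrow(hits_ba)) return(empty)
  check_cols(hits_ab, c("qseqid", "sseqid", "evalue", "bitscore"), "hits_ab")
  check_cols(hits_ba, c("qseqid", "sseqid", "evalue", "bitscore"), "hits_ba")

  best_ab <- hits_ab |>
    filter(.data$evalue <= evalue_cutoff) |>
    distinct() |>
    best_hit_per_query()
  best_ba <- hits_ba |>
    filter(.data$evalue <= evalue_cutoff) |>
    distinct() |>
    best_hit_per_query()
  if (!nrow(best_ab) || !nrow(best_ba)) return(empty)

  inner_join(
    best_ab |> select(paternal_gene = "qseqid", maternal_gene = "sseqid",
                      bitscore_ab = "bitscore"),
    best_ba |> select(maternal_gene = "qseqid", paternal_gene = "sseqid",
                      bitscore_ba = "bitscore"),
    by = c("paternal_gene", "maternal_gene")) |>
    arrange(.data$paternal_gene)
}
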