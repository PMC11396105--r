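#' Read gene models from a GFF3 file
#'
#' Imports gene/mRNA/exon features and resolves each exon to its gene through
#' the mRNA Parent chain. Coordinates stay 1-based inclusive as in GFF3;
#' interval arithmetic inside the package converts to 0-based half-open at
#' the point of use.
#'
#' @param path Path to a GFF3 file.
#' @return A `gene_models` list with two tibbles: `genes` (gene_id, chrom,
#'   start, end, strand) and `exons` (gene_id, chrom, start, end, strand).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("GFF3 file not found: %s", path))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) {
      abort(sprintf("Failed to parse GFF3 file %s: %s", path,
                    conditionMessage(e)))
    })
  df <- as_tibble(as.data.frame(gr)) |>
    rename(chrom = "seqnames")
  genes <- df |>
    filter(.data$type == "gene") |>
    mutate(gene_id = as.character(.data$ID)) |>
    select("gene_id", "chrom", "start", "end", "strand") |>
    mutate(chrom = as.character(.data$chrom), strand = as.character(.data$strand))
  mrna <- df |> filter(.data$type == "mRNA")
  mrna_to_gene <- setNames(vapply(mrna$Parent, function(p) as.character(p)[1],
                                  character(1)),
                           as.character(mrna$ID))
  exons <- df |>
    filter(.data$type == "exon") |>
    mutate(parent = vapply(.data$Parent, function(p) as.character(p)[1],
                           character(1)),
           gene_id = unname(mrna_to_gene[.data$parent])) |>
    mutate(gene_id = if_else(is.na(.data$gene_id), .data$parent, .data$gene_id)) |>
    select("gene_id", "chrom", "start", "end", "strand") |>
    mutate(chrom = as.character(.data$chrom), strand = as.character(.data$strand))
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

as_gene_models <- function(x) {
  if (inherits(x, "gene_models")) return(x)
  if (is.character(x) && length(x) == 1) return(read_gene_models(x))
  if (inherits(x, "hybrid_cross_sim")) {
    return(structure(list(genes = x$genes, exons = x$exons),
                     class = "gene_models"))
  }
  abort("`gene_models` must be a gene_models object, a GFF3 path, or a hybrid_cross_sim.")
}

tbl_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*")
}

#' Derive strand-aware gene regions
#'
#' Splits each gene into a gene body and fixed-width upstream / downstream
#' flanks, with upstream meaning 5' of the transcription start on the gene's
#' own strand. Flanks are truncated at position 1.
#'
#' @param gene_models A `gene_models` object (or GFF3 path).
#' @param flank Flank width in bp (default 2000).
#' @return A tibble with gene_id, chrom, start, end, strand and region
#'   (one of `upstream2kb`, `gene_body`, `downstream2kb`); 1-based inclusive.
#' @export
gene_regions <- function(gene_models, flank = 2000L) {
  gm <- as_gene_models(gene_models)
  g <- gm$genes
  plus <- g$strand != "-"
  up <- g |>
    mutate(start2 = if_else(plus, pmax(1L, .data$start - as.integer(flank)),
                            .data$end + 1L),
           end2 = if_else(plus, .data$start - 1L,
                          .data$end + as.integer(flank)),
           region = "upstream2kb")
  down <- g |>
    mutate(start2 = if_else(plus, .data$end + 1L,
                            pmax(1L, .data$start - as.integer(flank))),
           end2 = if_else(plus, .data$end + as.integer(flank),
                          .data$start - 1L),
           region = "downstream2kb")
  body <- g |> mutate(start2 = .data$start, end2 = .data$end,
                      region = "gene_body")
  bind_rows(body, up, down) |>
    filter(.data$end2 >= .data$start2, .data$start2 >= 1L) |>
    select("gene_id", "chrom", start = "start2", end = "end2", "strand",
           "region") |>
    arrange(.data$gene_id, .data$region)
}
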