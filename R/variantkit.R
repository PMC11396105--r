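#' Read a two-parent VCF into a tidy variant table
#'
#' Parses a VCF (plain or bgzipped) and returns one row per record with the
#' site-level hard-filter annotations (QD, FS, MQ) and, for every sample, a
#' genotype string column `gt_<sample>` and a genotype-quality column
#' `gq_<sample>`.
#'
#' @param path Path to a VCF file.
#' @return A tibble with columns chrom, pos, ref, alt, qd, fs, mq and the
#'   per-sample gt/gq columns.
#' @export
read_parent_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  out <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qd = suppressWarnings(as.numeric(vcfR::extract.info(vcf, "QD"))),
    fs = suppressWarnings(as.numeric(vcfR::extract.info(vcf, "FS"))),
    mq = suppressWarnings(as.numeric(vcfR::extract.info(vcf, "MQ"))))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gq <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  for (s in colnames(gt)) {
    out[[paste0("gt_", s)]] <- unname(gt[, s])
    out[[paste0("gq_", s)]] <- unname(gq[, s])
  }
  out
}

#' Hard-filter parental variant records
#'
#' Applies the GATK-style site filter: a record is removed when
#' `QD < 2.0 || FS > 60.0 || MQ < 40.0`, or when any parent's genotype
#' quality falls below `min_gq`. The inequalities are strict, so records
#' sitting exactly on a boundary (QD 2.0, FS 60.0, MQ 40.0, GQ 20) pass.
#' Records with a missing annotation fail conservatively; the number removed
#' per reason is attached as attribute `filter_tally`.
#'
#' @param variants Tibble from [read_parent_vcf()].
#' @param min_gq Minimum per-sample genotype quality (default 20).
#' @return The passing subset of `variants`, with a `filter_tally` attribute.
#' @export
hard_filter <- function(variants, min_gq = 20) {
  check_cols(variants, c("chrom", "pos", "qd", "fs", "mq"), "variant table")
  gq_cols <- grep("^gq_", names(variants), value = TRUE)
  if (!length(gq_cols)) abort("variant table has no gq_<sample> columns.")
  site_fail <- with(variants, qd < 2.0 | fs > 60.0 | mq < 40.0)
  site_fail <- site_fail | is.na(site_fail)
  gq_mat <- as.matrix(variants[gq_cols])
  gq_fail <- apply(gq_mat < min_gq | is.na(gq_mat), 1, any)
  keep <- !site_fail & !gq_fail
  out <- variants[keep, , drop = FALSE]
  attr(out, "filter_tally") <- c(
    n_input = nrow(variants),
    n_site_fail = sum(site_fail),
    n_gq_fail = sum(gq_fail & !site_fail),
    n_pass = sum(keep))
  out
}

parse_diploid_gt <- function(gt) {
  # returns a 2-column integer matrix of allele indices; NA rows = malformed
  parts <- stringr::str_match(gt, "^([0-9.])[/|]([0-9.])$")
  a1 <- suppressWarnings(as.integer(parts[, 2]))
  a2 <- suppressWarnings(as.integer(parts[, 3]))
  cbind(a1, a2)
}

#' Select parent-diagnostic SNPs
#'
#' Keeps biallelic SNP sites at which the two parents are homozygous for
#' different alleles (the 0/0 x 1/1 configuration and its mirror), so that
#' every hybrid read covering the site is assignable to one parent. Phased
#' and unphased genotype separators are treated alike: the notation encodes
#' homozygosity, not phasing. Multi-allelic sites, indels and records with a
#' malformed genotype are dropped with a tally.
#'
#' @param variants Tibble of (typically hard-filtered) variant records.
#' @param father,mother Sample names of the two parents as they appear in
#'   the VCF column header.
#' @param reference_side Which parental genome the variants were called
#'   against (`"paternal"` or `"maternal"`); carried through to the output.
#' @return A tibble of diagnostic SNPs: chrom, pos, paternal_allele,
#'   maternal_allele, reference_side, with a `selection_tally` attribute.
#' @export
select_diagnostic <- function(variants, father = "father", mother = "mother",
                              reference_side = c("paternal", "maternal")) {
  reference_side <- match.arg(reference_side)
  gt_f_col <- paste0("gt_", father)
  gt_m_col <- paste0("gt_", mother)
  if (!all(c(gt_f_col, gt_m_col) %in% names(variants))) {
    abort(sprintf(
      "Samples `%s` and `%s` not found in the variant table; available: %s.",
      father, mother,
      paste(sub("^gt_", "", grep("^gt_", names(variants), value = TRUE)),
            collapse = ", ")),
      class = "hybridscope_config_error")
  }
  check_cols(variants, c("chrom", "pos", "ref", "alt"), "variant table")

  multi <- stringr::str_detect(variants$alt, ",")
  snp <- nchar(variants$ref) == 1 & nchar(variants$alt) >= 1 &
    !multi & nchar(variants$alt) == 1
  gf <- parse_diploid_gt(variants[[gt_f_col]])
  gm <- parse_diploid_gt(variants[[gt_m_col]])
  malformed <- (rowSums(is.na(gf)) > 0 | rowSums(is.na(gm)) > 0) & !multi & snp
  hom_f <- gf[, 1] == gf[, 2]
  hom_m <- gm[, 1] == gm[, 2]
  divergent <- hom_f & hom_m & gf[, 1] != gm[, 1]
  keep <- snp & !malformed & !is.na(divergent) & divergent
  keep[is.na(keep)] <- FALSE

  sel <- variants[keep, , drop = FALSE]
  gf_k <- gf[keep, 1]
  gm_k <- gm[keep, 1]
  allele_of <- function(idx, ref, alt) if_else(idx == 0L, ref, alt)
  out <- tibble(
    chrom = sel$chrom,
    pos = sel$pos,
    paternal_allele = allele_of(gf_k, sel$ref, sel$alt),
    maternal_allele = allele_of(gm_k, sel$ref, sel$alt),
    reference_side = reference_side)
  attr(out, "selection_tally") <- c(
    n_input = nrow(variants),
    n_multiallelic_or_indel = sum(!snp),
    n_malformed_gt = sum(malformed),
    n_non_divergent = sum(snp & !malformed & !keep),
    n_diagnostic = nrow(out))
  out
}

#' Assign diagnostic SNPs to genes by exonic overlap
#'
#' A SNP receives the gene_id of every gene whose exons cover its position
#' (RNA-seq reads cover exons, so exonic overlap is the relevant criterion).
#' A SNP inside the exons of more than one gene yields one row per gene,
#' flagged `ambiguous`; intergenic or intronic SNPs keep `gene_id = NA`.
#'
#' @param snps Tibble of diagnostic SNPs (chrom, pos, ...).
#' @param gene_models A `gene_models` object, GFF3 path, or
#'   `hybrid_cross_sim`.
#' @return `snps` with gene_id and ambiguous columns, one row per
#'   (SNP, gene) pair.
#' @export
assign_to_genes <- function(snps, gene_models) {
  gm <- as_gene_models(gene_models)
  check_cols(snps, c("chrom", "pos"), "SNP table")
  if (!nrow(snps)) {
    return(mutate(snps, gene_id = character(), ambiguous = logical()))
  }
  snp_gr <- GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$pos, width = 1L))
  exon_gr <- tbl_to_granges(gm$exons)
  hits <- GenomicRanges::findOverlaps(snp_gr, exon_gr, ignore.strand = TRUE)
  hit_tbl <- tibble(
    snp_idx = S4Vectors::queryHits(hits),
    gene_id = gm$exons$gene_id[S4Vectors::subjectHits(hits)]) |>
    distinct()
  n_genes <- hit_tbl |> count(.data$snp_idx, name = "n_genes")
  hit_tbl <- left_join(hit_tbl, n_genes, by = "snp_idx")
  base <- mutate(snps, snp_idx = row_number())
  matched <- inner_join(base, hit_tbl, by = "snp_idx") |>
    mutate(ambiguous = .data$n_genes > 1L) |>
    select(-"n_genes")
  unmatched <- anti_join(base, hit_tbl, by = "snp_idx") |>
    mutate(gene_id = NA_character_, ambiguous = FALSE)
  bind_rows(matched, unmatched) |>
    arrange(.data$snp_idx) |>
    select(-"snp_idx")
}
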