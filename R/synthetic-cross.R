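#' Configuration for the synthetic hybrid-cross generator
#'
#' Bundles every knob of the simulated cross — two diverged parents and an F1
#' hybrid profiled by allele-resolved RNA-seq, whole-genome bisulfite
#' sequencing and bulk RNA-seq counts — into a validated list. The defaults
#' describe the reference study condition used throughout the package's own
#' validation: 200 genes, three biological replicates, a four-fold expression
#' ratio for planted biased genes, and planted differentially methylated
#' windows whose level shift is at least twice the per-context calling gate.
#'
#' @param n_genes Number of genes to simulate.
#' @param gene_length_range Two-element vector, min/max gene length in bp.
#' @param snps_per_gene Mean number of diagnostic SNPs per gene (Poisson).
#' @param frac_paternal_biased,frac_maternal_biased Proportions of genes with
#'   planted paternal / maternal allelic bias; their sum must not exceed 1.
#' @param bias_fold Expected paternal:maternal expression ratio of planted
#'   biased genes (must exceed 1); maternal-biased genes use its reciprocal.
#' @param n_replicates Number of hybrid RNA replicates.
#' @param rna_depth_per_gene Mean allele-informative reads per gene and
#'   replicate.
#' @param frac_dmr_genes Proportion of genes carrying a planted 200-bp
#'   differentially methylated window in the gene body.
#' @param dmr_delta Planted methylation-level shift in `[0, 1]`.
#' @param meth_baseline Named vector of per-context mean methylation levels
#'   for CG, CHG and CHH.
#' @param meth_coverage Mean read coverage per cytosine (Poisson).
#' @param frac_deg Proportion of genes planted as differentially expressed.
#' @param deg_log2fc Planted absolute log2 fold change of expression.
#' @param nb_dispersion Negative-binomial dispersion of the count matrix.
#' @param seed Master seed; every random stream is derived from it.
#'
#' @return A `cross_sim_config` list.
#' @seealso [simulate_cross()], [simulate_null_methylome()]
#' @export
cross_sim_config <- function(n_genes = 200,
                             gene_length_range = c(1200, 3000),
                             snps_per_gene = 5,
                             frac_paternal_biased = 0.15,
                             frac_maternal_biased = 0.10,
                             bias_fold = 4,
                             n_replicates = 3,
                             rna_depth_per_gene = 60,
                             frac_dmr_genes = 0.10,
                             dmr_delta = 0.5,
                             meth_baseline = c(CG = 0.8, CHG = 0.3, CHH = 0.1),
                             meth_coverage = 20,
                             frac_deg = 0.10,
                             deg_log2fc = 2,
                             nb_dispersion = 0.05,
                             seed = 1L) {
  assert_count(n_genes, "n_genes")
  assert_count(n_replicates, "n_replicates")
  assert_prop(frac_paternal_biased, "frac_paternal_biased")
  assert_prop(frac_maternal_biased, "frac_maternal_biased")
  assert_prop(frac_dmr_genes, "frac_dmr_genes")
  assert_prop(frac_deg, "frac_deg")
  assert_prop(dmr_delta, "dmr_delta")
  if (frac_paternal_biased + frac_maternal_biased > 1) {
    abort("`frac_paternal_biased` + `frac_maternal_biased` must not exceed 1.",
          class = "hybridscope_config_error")
  }
  if (!is.numeric(bias_fold) || bias_fold <= 1) {
    abort("`bias_fold` must be a ratio greater than 1.",
          class = "hybridscope_config_error")
  }
  if (length(gene_length_range) != 2 || any(gene_length_range < 200) ||
      diff(gene_length_range) < 0) {
    abort("`gene_length_range` must be an increasing bp interval >= 200.",
          class = "hybridscope_config_error")
  }
  if (is.null(names(meth_baseline)) ||
      !all(c("CG", "CHG", "CHH") %in% names(meth_baseline))) {
    abort("`meth_baseline` must be named with CG, CHG and CHH entries.",
          class = "hybridscope_config_error")
  }
  for (ctx in c("CG", "CHG", "CHH")) {
    assert_prop(unname(meth_baseline[[ctx]]), paste0("meth_baseline[", ctx, "]"))
  }
  if (!is.numeric(meth_coverage) || meth_coverage < 0) {
    abort("`meth_coverage` must be non-negative.",
          class = "hybridscope_config_error")
  }
  if (!is.numeric(snps_per_gene) || snps_per_gene < 0) {
    abort("`snps_per_gene` must be non-negative.",
          class = "hybridscope_config_error")
  }
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0) {
    abort("`nb_dispersion` must be positive.",
          class = "hybridscope_config_error")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      gene_length_range = as.integer(gene_length_range),
      snps_per_gene = snps_per_gene,
      frac_paternal_biased = frac_paternal_biased,
      frac_maternal_biased = frac_maternal_biased,
      bias_fold = bias_fold,
      n_replicates = as.integer(n_replicates),
      rna_depth_per_gene = rna_depth_per_gene,
      frac_dmr_genes = frac_dmr_genes,
      dmr_delta = dmr_delta,
      meth_baseline = meth_baseline[c("CG", "CHG", "CHH")],
      meth_coverage = meth_coverage,
      frac_deg = frac_deg,
      deg_log2fc = deg_log2fc,
      nb_dispersion = nb_dispersion,
      seed = as.integer(seed)
    ),
    class = "cross_sim_config"
  )
}

# Gene layout: 50 genes per pseudo-chromosome, non-overlapping, alternating
# strands, >= 5 kb between neighbours so the 2 kb flanks never collide.
sim_gene_models <- function(config) {
  with_stream_seed(config$seed, "gene_models", {
    n <- config$n_genes
    lens <- round(runif(n, config$gene_length_range[1], config$gene_length_range[2]))
    chrom_idx <- (seq_len(n) - 1L) %/% 50L + 1L
    genes <- vector("list", n)
    cur <- 3001L
    for (i in seq_len(n)) {
      if (i > 1 && chrom_idx[i] != chrom_idx[i - 1]) cur <- 3001L
      start <- cur
      end <- start + lens[i] - 1L
      cur <- end + 5001L
      genes[[i]] <- tibble(
        gene_id = sprintf("g%04d", i),
        chrom = paste0("chr", chrom_idx[i]),
        start = start, end = end,
        strand = if (i %% 2 == 1) "+" else "-",
        length = lens[i]
      )
    }
    bind_rows(genes)
  })
}

sim_exons <- function(genes) {
  # two exons separated by a short intron; SNPs land in exons only
  genes |>
    mutate(
      intron_len = pmax(50L, round(0.1 * .data$length)),
      e1_len = round(0.45 * (.data$length - .data$intron_len)),
      exon1_start = .data$start,
      exon1_end = .data$start + .data$e1_len - 1L,
      exon2_start = .data$exon1_end + .data$intron_len + 1L,
      exon2_end = .data$end
    ) |>
    select("gene_id", "chrom", "strand",
           "exon1_start", "exon1_end", "exon2_start", "exon2_end") |>
    tidyr::pivot_longer(cols = dplyr::starts_with("exon"),
                        names_to = c("exon", ".value"),
                        names_pattern = "(exon[12])_(start|end)") |>
    mutate(exon_id = paste0(.data$gene_id, ".", sub("exon", "e", .data$exon))) |>
    select("gene_id", "exon_id", "chrom", "start", "end", "strand")
}

sim_diagnostic_snps <- function(config, genes, exons) {
  with_stream_seed(config$seed, "snps", {
    per_gene <- rpois(nrow(genes), config$snps_per_gene)
    out <- vector("list", nrow(genes))
    for (i in seq_len(nrow(genes))) {
      k <- per_gene[i]
      if (k == 0) next
      ex <- exons[exons$gene_id == genes$gene_id[i], ]
      exonic <- unlist(Map(seq.int, ex$start, ex$end), use.names = FALSE)
      k <- min(k, length(exonic))
      pos <- sort(sample(exonic, k))
      out[[i]] <- tibble(
        chrom = genes$chrom[i], pos = pos,
        gene_id = genes$gene_id[i],
        ref = "A", alt = "G",
        paternal_allele = "A", maternal_allele = "G"
      )
    }
    bind_rows(out)
  })
}

# Non-diagnostic and low-quality records mixed into the VCF so the hard
# filter and genotype screen have something to reject.
sim_decoy_variants <- function(config, genes) {
  with_stream_seed(config$seed, "decoys", {
    chroms <- unique(genes$chrom)
    types <- c("het", "low_qd", "high_fs", "low_mq", "low_gq",
               "same_hom", "multiallelic")
    out <- list()
    j <- 0L
    for (chrom in chroms) {
      pos <- sample(200:2800, length(types))   # upstream of the first gene
      for (t in seq_along(types)) {
        j <- j + 1L
        out[[j]] <- tibble(chrom = chrom, pos = pos[t], type = types[t])
      }
    }
    bind_rows(out) |> arrange(.data$chrom, .data$pos)
  })
}

vcf_header <- function(chrom_lengths) {
  c("##fileformat=VCFv4.2",
    "##source=hybridscope_sim",
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths), chrom_lengths),
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "father", "mother", sep = "\t"))
}

write_parent_vcf <- function(snps, decoys, chrom_lengths, path) {
  diag_rows <- sprintf(
    "%s\t%d\t.\tA\tG\t100\t.\tQD=%.1f;FS=%.1f;MQ=%.1f\tGT:GQ\t0/0:%d\t1/1:%d",
    snps$chrom, snps$pos, snps$qd, snps$fs, snps$mq, snps$gq_father,
    snps$gq_mother)
  decoy_rows <- vapply(seq_len(nrow(decoys)), function(i) {
    d <- decoys[i, ]
    base <- function(info, f, m) {
      sprintf("%s\t%d\t.\tC\tT\t80\t.\t%s\tGT:GQ\t%s\t%s",
              d$chrom, d$pos, info, f, m)
    }
    switch(d$type,
      het = base("QD=25.0;FS=2.0;MQ=60.0", "0/1:90", "0/0:90"),
      low_qd = base("QD=1.5;FS=2.0;MQ=60.0", "0/0:90", "1/1:90"),
      high_fs = base("QD=25.0;FS=75.0;MQ=60.0", "0/0:90", "1/1:90"),
      low_mq = base("QD=25.0;FS=2.0;MQ=30.0", "0/0:90", "1/1:90"),
      low_gq = base("QD=25.0;FS=2.0;MQ=60.0", "0/0:12", "1/1:90"),
      same_hom = base("QD=25.0;FS=2.0;MQ=60.0", "1/1:90", "1/1:90"),
      multiallelic = sprintf(
        "%s\t%d\t.\tC\tT,G\t80\t.\tQD=25.0;FS=2.0;MQ=60.0\tGT:GQ\t1/1:90\t2/2:90",
        d$chrom, d$pos))
  }, character(1))
  body <- tibble(chrom = c(snps$chrom, decoys$chrom),
                 pos = c(snps$pos, decoys$pos),
                 line = c(diag_rows, decoy_rows)) |>
    arrange(.data$chrom, .data$pos)
  writeLines(c(vcf_header(chrom_lengths), body$line), path)
  invisible(path)
}

write_gff3 <- function(genes, exons, path) {
  gl <- sprintf("%s\thybridscope_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                genes$chrom, genes$start, genes$end, genes$strand,
                genes$gene_id)
  ml <- sprintf("%s\thybridscope_sim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                genes$chrom, genes$start, genes$end, genes$strand,
                genes$gene_id, genes$gene_id)
  el <- sprintf("%s\thybridscope_sim\texon\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s.t1",
                exons$chrom, exons$start, exons$end, exons$strand,
                exons$exon_id, exons$gene_id)
  key <- c(genes$gene_id, genes$gene_id, exons$gene_id)
  ord <- order(key, c(rep(1L, nrow(genes)), rep(2L, nrow(genes)),
                      rep(3L, nrow(exons))))
  writeLines(c("##gff-version 3", c(gl, ml, el)[ord]), path)
  invisible(path)
}

write_fasta_stub <- function(chrom_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(chrom_lengths)) {
    writeLines(paste0(">", chrom), con)
    len <- chrom_lengths[[chrom]]
    full <- len %/% 60L
    if (full > 0) writeLines(rep(strrep("A", 60L), full), con)
    if (len %% 60L > 0) writeLines(strrep("A", len %% 60L), con)
  }
  invisible(path)
}

sim_allele_depths <- function(config, snps, bias_by_gene) {
  bf <- config$bias_fold
  p_pat <- c(paternal = bf / (bf + 1), maternal = 1 / (bf + 1), none = 0.5)
  gene_snps <- split(seq_len(nrow(snps)), snps$gene_id)
  with_stream_seed(config$seed, "allele_depths", {
    reps <- vector("list", config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
      rows <- vector("list", length(gene_snps))
      for (gi in seq_along(gene_snps)) {
        idx <- gene_snps[[gi]]
        gid <- names(gene_snps)[gi]
        total <- rpois(1, config$rna_depth_per_gene)
        alloc <- as.integer(stats::rmultinom(1, total, rep(1, length(idx))))
        pat <- rbinom(length(idx), alloc, p_pat[[bias_by_gene[[gid]]]])
        rows[[gi]] <- tibble(
          chrom = snps$chrom[idx], pos = snps$pos[idx], gene_id = gid,
          replicate = paste0("rep", r),
          pat_count = pat, mat_count = alloc - pat)
      }
      reps[[r]] <- bind_rows(rows)
    }
    bind_rows(reps) |> arrange(.data$replicate, .data$chrom, .data$pos)
  })
}

# Cytosine site scaffold over gene bodies plus 2 kb flanks. Densities give
# roughly 11 CG, 11 CHG and 28 CHH sites per 200-bp window, comfortably above
# the per-context minimum site counts used by the DMR caller.
sim_meth_site_scaffold <- function(config, genes) {
  with_stream_seed(config$seed, "meth_sites", {
    out <- vector("list", nrow(genes))
    for (i in seq_len(nrow(genes))) {
      lo <- max(1L, genes$start[i] - 2000L)
      hi <- genes$end[i] + 2000L
      len <- hi - lo + 1L
      n_ctx <- c(CG = round(len / 18), CHG = round(len / 18), CHH = round(len / 7))
      pos <- lo - 1L + sample.int(len, sum(n_ctx))
      out[[i]] <- tibble(
        chrom = genes$chrom[i],
        pos = pos,
        strand = sample(c("+", "-"), sum(n_ctx), replace = TRUE),
        context = rep(names(n_ctx), n_ctx),
        gene_id = genes$gene_id[i])
    }
    bind_rows(out) |> arrange(.data$chrom, .data$pos)
  })
}

# Planted DMR windows: one 200-bp tile centred in the gene body. The shift
# direction is chosen per context toward the feasible side of [0, 1] so the
# full configured delta is realised (CG baseline 0.8 shifts down, CHG/CHH
# baselines 0.3/0.1 shift up under the defaults).
plan_dmr_windows <- function(config, genes, dmr_gene_ids) {
  base <- config$meth_baseline
  purrr::map_dfr(dmr_gene_ids, function(gid) {
    g <- genes[genes$gene_id == gid, ]
    mid <- (g$start + g$end) %/% 2
    w0 <- ((mid - 1L) %/% 200L) * 200L          # 0-based window start
    tibble(
      chrom = g$chrom, start = w0, end = w0 + 200L,
      context = c("CG", "CHG", "CHH"),
      direction = ifelse(base[c("CG", "CHG", "CHH")] +
                           config$dmr_delta <= 0.98, "hyper", "hypo"),
      gene_id = gid)
  })
}

sim_meth_counts <- function(config, scaffold, dmr_plan, group) {
  base <- config$meth_baseline
  level <- unname(base[scaffold$context])
  if (group == "hybrid" && nrow(dmr_plan)) {
    for (i in seq_len(nrow(dmr_plan))) {
      w <- dmr_plan[i, ]
      hit <- scaffold$chrom == w$chrom & scaffold$context == w$context &
        scaffold$pos - 1L >= w$start & scaffold$pos - 1L < w$end
      shift <- if (w$direction == "hyper") config$dmr_delta else -config$dmr_delta
      level[hit] <- pmin(0.98, pmax(0.02, level[hit] + shift))
    }
  }
  with_stream_seed(config$seed, paste0("meth_counts_", group), {
    cov <- rpois(nrow(scaffold), config$meth_coverage)
    m <- rbinom(nrow(scaffold), cov, level)
    scaffold |>
      mutate(count_m = m, count_u = cov - m) |>
      select("chrom", "pos", "strand", "context", "count_m", "count_u")
  })
}

sim_counts_matrix <- function(config, genes, deg_by_gene) {
  with_stream_seed(config$seed, "counts", {
    n <- nrow(genes)
    mu <- rlnorm(n, meanlog = log(100), sdlog = 1)
    fc <- 2^config$deg_log2fc
    mu_h <- mu * ifelse(deg_by_gene == "up", fc,
                        ifelse(deg_by_gene == "down", 1 / fc, 1))
    size <- 1 / config$nb_dispersion
    cols <- list()
    for (r in seq_len(config$n_replicates)) {
      cols[[paste0("hybrid_", r)]] <- rnbinom(n, size = size, mu = mu_h)
    }
    for (r in seq_len(config$n_replicates)) {
      cols[[paste0("maternal_", r)]] <- rnbinom(n, size = size, mu = mu)
    }
    dplyr::bind_cols(tibble(gene_id = genes$gene_id), as_tibble(cols))
  })
}

sim_ortholog_hits <- function(config, genes) {
  with_stream_seed(config$seed, "orthologs", {
    pat <- genes$gene_id
    mat <- sub("^g", "m", pat)
    n <- length(pat)
    true_score <- round(300 + runif(n, 0, 50), 1)
    base_cols <- function(q, s, score, eval) {
      tibble(qseqid = q, sseqid = s, pident = 95, length = 400, mismatch = 20,
             gapopen = 1, qstart = 1, qend = 400, sstart = 1, send = 400,
             evalue = eval, bitscore = score)
    }
    ab <- base_cols(pat, mat, true_score, 1e-80)
    ba <- base_cols(mat, pat, true_score, 1e-80)
    n_decoy <- max(1L, round(0.3 * n))
    dq <- sample(n, n_decoy)
    ds <- sample(n, n_decoy)
    keep <- dq != ds
    decoy_ab <- base_cols(pat[dq[keep]], mat[ds[keep]],
                          round(runif(sum(keep), 80, 120), 1), 1e-8)
    decoy_ba <- base_cols(mat[ds[keep]], pat[dq[keep]],
                          round(runif(sum(keep), 80, 120), 1), 1e-8)
    n_weak <- max(1L, round(0.1 * n))
    wq <- sample(n, n_weak)
    weak_ab <- base_cols(pat[wq], mat[sample(n, n_weak)], 500, 1e-3)
    list(
      ab = bind_rows(ab, ab[1, ], decoy_ab, weak_ab),
      ba = bind_rows(ba, decoy_ba),
      pairs = tibble(paternal_gene = pat, maternal_gene = mat))
  })
}

#' Simulate a complete hybrid-cross dataset with known ground truth
#'
#' Generates, under a single master seed, every input the downstream stages
#' consume: a parental VCF with homozygous-divergent diagnostic SNPs (plus
#' low-quality and non-diagnostic decoy records), GFF3 gene models, a
#' placeholder genome FASTA, per-replicate hybrid allele-depth tables,
#' cytosine-report methylation tables for the hybrid and maternal groups with
#' planted 200-bp differential windows, a negative-binomial count matrix with
#' planted differentially expressed genes, reciprocal similarity-hit tables
#' linking the two parental gene sets, and a JSON ground-truth manifest.
#' Identical configuration and seed reproduce every file byte for byte.
#'
#' @param config A [cross_sim_config()].
#' @param dir Output directory; created if needed.
#' @return Invisibly, a `hybrid_cross_sim` object: the configuration, file
#'   paths, the gene/SNP tables, all simulated tables in memory, and a
#'   `truth` list with per-gene bias labels, planted DMR windows, per-gene
#'   DEG labels and the true ortholog pairing.
#' @export
simulate_cross <- function(config, dir = tempfile("hybrid_cross_")) {
  stopifnot(inherits(config, "cross_sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  genes <- sim_gene_models(config)
  exons <- sim_exons(genes)
  chrom_lengths <- genes |>
    group_by(.data$chrom) |>
    summarise(len = max(.data$end) + 3000L) |>
    (\(d) setNames(d$len, d$chrom))()

  snps <- sim_diagnostic_snps(config, genes, exons)
  snps$qd <- 28.0
  snps$fs <- 1.5
  snps$mq <- 60.0
  snps$gq_father <- 95L
  snps$gq_mother <- 95L
  decoys <- sim_decoy_variants(config, genes)

  labels <- with_stream_seed(config$seed, "gene_labels", {
    n <- config$n_genes
    n_pat <- round(config$frac_paternal_biased * n)
    n_mat <- round(config$frac_maternal_biased * n)
    bias <- rep("none", n)
    picked <- sample(n, n_pat + n_mat)
    bias[picked[seq_len(n_pat)]] <- "paternal"
    if (n_mat > 0) bias[picked[n_pat + seq_len(n_mat)]] <- "maternal"
    n_dmr <- round(config$frac_dmr_genes * n)
    dmr_ids <- genes$gene_id[sample(n, n_dmr)]
    n_deg <- round(config$frac_deg * n)
    deg <- rep("ns", n)
    deg_idx <- sample(n, n_deg)
    deg[deg_idx] <- sample(c("up", "down"), n_deg, replace = TRUE)
    list(bias = setNames(bias, genes$gene_id),
         dmr_ids = sort(dmr_ids),
         deg = setNames(deg, genes$gene_id))
  })

  depths <- sim_allele_depths(config, snps, labels$bias)
  dmr_plan <- plan_dmr_windows(config, genes, labels$dmr_ids)
  scaffold <- sim_meth_site_scaffold(config, genes)
  meth_hybrid <- sim_meth_counts(config, scaffold, dmr_plan, "hybrid")
  meth_maternal <- sim_meth_counts(config, scaffold, dmr_plan, "maternal")
  counts <- sim_counts_matrix(config, genes, unname(labels$deg))
  orth <- sim_ortholog_hits(config, genes)

  paths <- list(
    vcf = file.path(dir, "parents.vcf"),
    gff = file.path(dir, "genes.gff3"),
    fasta = file.path(dir, "genome.fa"),
    allele_depth = file.path(
      dir, sprintf("allele_depth_rep%d.tsv", seq_len(config$n_replicates))),
    meth_hybrid = file.path(dir, "meth_hybrid.cx.tsv"),
    meth_maternal = file.path(dir, "meth_maternal.cx.tsv"),
    counts = file.path(dir, "counts.tsv"),
    hits_ab = file.path(dir, "hits_pat_vs_mat.tsv"),
    hits_ba = file.path(dir, "hits_mat_vs_pat.tsv"),
    truth = file.path(dir, "ground_truth.json"))

  write_parent_vcf(snps, decoys, chrom_lengths, paths$vcf)
  write_gff3(genes, exons, paths$gff)
  write_fasta_stub(chrom_lengths, paths$fasta)
  for (r in seq_len(config$n_replicates)) {
    write_tsv_plain(filter(depths, .data$replicate == paste0("rep", r)),
                    paths$allele_depth[r])
  }
  write_tsv_plain(meth_hybrid, paths$meth_hybrid)
  write_tsv_plain(meth_maternal, paths$meth_maternal)
  write_tsv_plain(counts, paths$counts)
  write_tsv_plain(orth$ab, paths$hits_ab)
  write_tsv_plain(orth$ba, paths$hits_ba)

  truth <- list(
    biased_genes = tibble(gene_id = names(labels$bias),
                          bias = unname(labels$bias)),
    dmr_windows = dmr_plan,
    deg_genes = tibble(gene_id = names(labels$deg),
                       status = unname(labels$deg)),
    ortholog_pairs = orth$pairs)
  jsonlite::write_json(
    list(config = unclass(config),
         biased_genes = as.list(labels$bias),
         dmr_windows = dmr_plan,
         deg_genes = as.list(labels$deg)),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(
    list(config = config, dir = dir, paths = paths,
         genes = genes, exons = exons, snps = as_tibble(snps),
         tables = list(allele_depths = depths,
                       meth = list(hybrid = meth_hybrid,
                                   maternal = meth_maternal),
                       counts = counts,
                       hits_ab = orth$ab, hits_ba = orth$ba),
         truth = truth),
    class = "hybrid_cross_sim")
}

#' @export
print.hybrid_cross_sim <- function(x, ...) {
  cat("<hybrid_cross_sim>\n")
  cat("  genes:", nrow(x$genes), " diagnostic SNPs:", nrow(x$snps), "\n")
  cat("  replicates:", x$config$n_replicates,
      " planted biased genes:", sum(x$truth$biased_genes$bias != "none"), "\n")
  cat("  planted DMR windows:", nrow(x$truth$dmr_windows),
      " planted DEGs:", sum(x$truth$deg_genes$status != "ns"), "\n")
  cat("  dir:", x$dir, "\n")
  invisible(x)
}

#' Simulate a null methylome: two groups drawn from identical site levels
#'
#' Builds a cytosine scaffold over tiled 200-bp windows and draws methylated /
#' unmethylated counts for two groups from exactly the same per-site level
#' (the per-context baseline of `config`), so any differential call on the
#' result is a false positive. Used to measure the type-I error of the DMR
#' and DMC callers.
#'
#' @param config A [cross_sim_config()]; `meth_baseline`, `meth_coverage` and
#'   `seed` are used.
#' @param n_windows Number of 200-bp windows to scaffold.
#' @param dir Optional directory; when given, the two cytosine reports are
#'   also written as TSV.
#' @return A list with tibbles `group_a` and `group_b` in cytosine-report
#'   layout (chrom, pos, strand, context, count_m, count_u). A mean coverage
#'   of zero yields empty tables.
#' @export
simulate_null_methylome <- function(config, n_windows = 2000, dir = NULL) {
  stopifnot(inherits(config, "cross_sim_config"))
  assert_count(n_windows, "n_windows")
  empty <- tibble(chrom = character(), pos = integer(), strand = character(),
                  context = character(), count_m = integer(),
                  count_u = integer())
  if (config$meth_coverage == 0) {
    return(list(group_a = empty, group_b = empty))
  }
  span <- n_windows * 200L
  scaffold <- with_stream_seed(config$seed, "null_meth_sites", {
    n_ctx <- c(CG = round(span / 18), CHG = round(span / 18),
               CHH = round(span / 7))
    tibble(
      chrom = "null1",
      pos = sample.int(span, sum(n_ctx)),
      strand = sample(c("+", "-"), sum(n_ctx), replace = TRUE),
      context = rep(names(n_ctx), n_ctx)) |>
      arrange(.data$pos)
  })
  level <- unname(config$meth_baseline[scaffold$context])
  draw <- function(label) {
    with_stream_seed(config$seed, paste0("null_meth_", label), {
      cov <- rpois(nrow(scaffold), config$meth_coverage)
      m <- rbinom(nrow(scaffold), cov, level)
      scaffold |> mutate(count_m = m, count_u = cov - m)
    })
  }
  out <- list(group_a = draw("a"), group_b = draw("b"))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_plain(out$group_a, file.path(dir, "null_group_a.cx.tsv"))
    write_tsv_plain(out$group_b, file.path(dir, "null_group_b.cx.tsv"))
  }
  out
}
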