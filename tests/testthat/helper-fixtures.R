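# Shared fixtures, built once per test run. The reference simulation uses
# the package's default study condition (200 genes, bias fold 4, depth 60,
# three replicates, DMR delta twice the CG gate, coverage 20).

fixture_env <- new.env(parent = emptyenv())

reference_sim <- function() {
  if (is.null(fixture_env$sim)) {
    fixture_env$sim <- simulate_cross(cross_sim_config(seed = 1L))
  }
  fixture_env$sim
}

reference_run <- function() {
  if (is.null(fixture_env$run)) {
    fixture_env$run <- suppressMessages(
      run_pipeline(pipeline_config(sim = cross_sim_config(seed = 1L)),
                   sim = reference_sim()))
  }
  fixture_env$run
}

small_sim <- function(seed = 11L, n_genes = 40L, ...) {
  key <- paste0("small_", seed, "_", n_genes)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- simulate_cross(
      cross_sim_config(n_genes = n_genes, seed = seed, ...))
  }
  fixture_env[[key]]
}

# A two-gene annotation with overlapping exons, built in code.
toy_gene_models <- function() {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"),
    chrom = "chr1",
    start = c(100L, 350L),
    end = c(400L, 700L),
    strand = c("+", "-"))
  exons <- tibble::tibble(
    gene_id = c("gA", "gA", "gB"),
    chrom = "chr1",
    start = c(100L, 300L, 350L),
    end = c(200L, 400L, 700L),
    strand = c("+", "+", "-"))
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

toy_sites <- function(chrom, pos, context, m, u, strand = "+") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos),
                 strand = strand, context = context,
                 count_m = as.integer(m), count_u = as.integer(u))
}

# Independent two-sided Fisher oracle: hypergeometric enumeration over the
# support, summing outcomes no more probable than the observed table.
fisher_oracle <- function(m_a, u_a, m_b, u_b) {
  white <- m_a + m_b
  black <- u_a + u_b
  drawn <- m_a + u_a
  support <- max(0, drawn - black):min(drawn, white)
  dens <- stats::dhyper(support, white, black, drawn)
  p_obs <- stats::dhyper(m_a, white, black, drawn)
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

# Independent two-sided exact binomial oracle at p = 0.5 by tail
# enumeration.
binom_oracle <- function(k, n) {
  dens <- stats::dbinom(0:n, n, 0.5)
  sum(dens[dens <= dens[k + 1] * (1 + 1e-7)])
}

# Brute-force reciprocal-best-hit oracle for small tables.
rbh_oracle <- function(ab, ba, cutoff = 1e-5) {
  best <- function(hits, q) {
    h <- hits[hits$qseqid == q & hits$evalue <= cutoff, ]
    if (!nrow(h)) return(NA_character_)
    h <- h[order(-h$bitscore, h$evalue, h$sseqid), ]
    h$sseqid[1]
  }
  pairs <- list()
  for (q in unique(ab$qseqid[ab$evalue <= cutoff])) {
    b <- best(ab, q)
    if (!is.na(b) && identical(best(ba, b), q)) {
      pairs[[length(pairs) + 1]] <- c(q, b)
    }
  }
  if (!length(pairs)) {
    return(tibble::tibble(paternal_gene = character(),
                          maternal_gene = character()))
  }
  m <- do.call(rbind, pairs)
  tibble::tibble(paternal_gene = m[, 1], maternal_gene = m[, 2]) |>
    dplyr::arrange(paternal_gene)
}
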