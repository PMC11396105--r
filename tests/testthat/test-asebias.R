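ac_row <- function(gene, rep, pat, mat) {
  tibble::tibble(gene_id = gene, replicate = rep,
                 pat_count = as.integer(pat), mat_count = as.integer(mat))
}

three_reps <- function(gene, pat, mat) {
  dplyr::bind_rows(lapply(paste0("rep", 1:3), function(r)
    ac_row(gene, r, pat, mat)))
}

test_that("allele counting is additive over a gene's SNPs", {
  depths <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L),
    gene_id = c("gA", "gA", NA), replicate = "rep1",
    pat_count = c(10L, 5L, 99L), mat_count = c(3L, 2L, 99L))
  out <- count_alleles(depths)
  expect_identical(nrow(out), 1L)
  expect_identical(out$pat_count, 15L)
  expect_identical(out$mat_count, 5L)
})

test_that("rows are joined to diagnostics by position; unmatched rows are tallied", {
  depths <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 99L), replicate = "rep1",
    pat_count = c(4L, 6L, 1L), mat_count = c(1L, 2L, 1L))
  diag <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L), gene_id = "gA")
  out <- count_alleles(depths, diagnostics = diag)
  expect_identical(out$pat_count, 10L)
  expect_identical(unname(attr(out, "join_tally")["n_unmatched_rows"]), 1L)
  empty <- count_alleles(depths[0, ], diagnostics = diag)
  expect_identical(nrow(empty), 0L)
})

test_that("the per-replicate binomial p matches tail enumeration exactly", {
  calls <- test_bias(three_reps("gA", 20, 5))
  reps <- tidy(calls)
  expect_identical(nrow(reps), 3L)
  expect_true(all(abs(reps$p - binom_oracle(20, 25)) < 1e-12))
  expect_true(all(abs(reps$p - 0.004077315) < 1e-8))
  expect_true(all(reps$ratio == 4))
  expect_identical(calls$classification, "paternal")
})

test_that("the ratio and q gates classify exactly as printed", {
  # symmetric counts: unbiased
  expect_identical(test_bias(three_reps("gA", 30, 30))$classification,
                   "unbiased")
  # ratio 1.5 below the gate: unbiased regardless of q
  expect_identical(test_bias(three_reps("gA", 15, 10))$classification,
                   "unbiased")
  # maternal mirror of the paternal example
  expect_identical(test_bias(three_reps("gA", 5, 20))$classification,
                   "maternal")
  # one replicate failing the ratio gate blocks the call
  mixed <- dplyr::bind_rows(ac_row("gA", "rep1", 40, 5),
                            ac_row("gA", "rep2", 40, 5),
                            ac_row("gA", "rep3", 30, 20))
  expect_identical(test_bias(mixed)$classification, "unbiased")
})

test_that("infinite ratios from a zero maternal count satisfy the paternal gate", {
  calls <- test_bias(three_reps("gA", 25, 0))
  expect_identical(calls$classification, "paternal")
  expect_identical(calls$ratio, Inf)
})

test_that("low-coverage genes are never classified", {
  calls <- test_bias(three_reps("gA", 7, 0), min_total = 10)
  expect_identical(calls$classification, "unbiased")
  expect_true(calls$low_coverage)
})

test_that("swapping parental labels maps paternal calls to maternal calls exactly", {
  sim <- small_sim()
  counts <- count_alleles(sim$tables$allele_depths,
                          diagnostics = sim$snps)
  fwd <- test_bias(counts)
  swapped <- counts |>
    dplyr::rename(pat_count = mat_count, mat_count = pat_count)
  rev <- test_bias(swapped)
  map <- c(paternal = "maternal", maternal = "paternal",
           unbiased = "unbiased")
  expect_identical(unname(map[fwd$classification]), rev$classification)
})

test_that("q-values are nondecreasing in raw p rank within each replicate", {
  sim <- small_sim()
  counts <- count_alleles(sim$tables$allele_depths, diagnostics = sim$snps)
  reps <- tidy(test_bias(counts))
  for (r in unique(reps$replicate)) {
    d <- dplyr::arrange(dplyr::filter(reps, replicate == r), p)
    expect_true(all(diff(d$q) >= -1e-12))
  }
})

test_that("pooled mode aggregates replicates before testing", {
  # each replicate is underpowered; the pooled counts are not
  weak <- three_reps("gA", 12, 4)
  expect_identical(test_bias(weak)$classification, "unbiased")
  pooled <- test_bias(weak, mode = "pooled")
  expect_identical(pooled$classification, "paternal")
  expect_lt(abs(tidy(pooled)$p - binom_oracle(36, 48)), 1e-12)
})

test_that("dominance summary partitions shared bias DEGs by direction", {
  bias_a <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
                           classification = c("paternal", "paternal",
                                              "maternal", "paternal"))
  bias_b <- tibble::tibble(gene_id = c("m1", "m2", "m3"),
                           classification = c("paternal", "paternal",
                                              "maternal"))
  deg_a <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
                          status = c("up", "up", "down", "up"))
  deg_b <- tibble::tibble(gene_id = c("m1", "m2", "m3"),
                          status = c("up", "down", "down"))
  orth <- tibble::tibble(paternal_gene = c("g1", "g2", "g3"),
                         maternal_gene = c("m1", "m2", "m3"))
  ds <- dominance_summary(bias_a, bias_b, deg_a, deg_b, orthologs = orth)
  g <- glance(ds)
  # g1 up/up, g2 up/down (mixed), g3 down/down; g4 has no counterpart
  expect_identical(g$shared, 3L)
  expect_identical(g$shared_up, 1L)
  expect_identical(g$shared_down, 1L)
  expect_identical(g$shared_mixed, 1L)
  expect_identical(g$shared_up + g$shared_down + g$shared_mixed, g$shared)
  expect_identical(g$total_paternal_bias, 3L)
  expect_identical(g$total_maternal_bias, 1L)
})

test_that("an empty bias set yields zero counts and an undefined comparison", {
  bias_a <- tibble::tibble(gene_id = "g1", classification = "paternal")
  bias_b <- tibble::tibble(gene_id = character(),
                           classification = character())
  fpkm_a <- tibble::tibble(gene_id = "g1", fpkm = 12)
  ds <- dominance_summary(bias_a, bias_b, fpkm_a = fpkm_a)
  expr <- ds$expression
  mat_row <- expr[expr$reference == "paternal_ref" &
                    expr$classification == "maternal", ]
  expect_false(mat_row$defined)
  expect_true(is.na(mat_row$mean_fpkm))
  expect_identical(glance(ds)$shared, 0L)
})
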