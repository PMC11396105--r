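test_that("the FPKM identity holds exactly", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(100L, 0L))
  lens <- tibble::tibble(gene_id = c("g1", "g2"), length = c(1000, 500))
  out <- compute_fpkm(counts, lens, library_sizes = c(s1 = 1e6))
  expect_identical(out$fpkm[out$gene_id == "g1"], 100)
  expect_identical(out$fpkm[out$gene_id == "g2"], 0)
  # doubling the library size halves FPKM
  half <- compute_fpkm(counts, lens, library_sizes = c(s1 = 2e6))
  expect_equal(half$fpkm, out$fpkm / 2)
  expect_error(compute_fpkm(counts, lens, library_sizes = c(s1 = 0)),
               class = "hybridscope_config_error")
})

test_that("FPKM identity holds to high relative precision on simulated data", {
  sim <- small_sim()
  fp <- compute_fpkm(sim$tables$counts,
                     dplyr::select(sim$genes, gene_id, length))
  rel <- with(dplyr::filter(fp, count > 0),
              abs(fpkm - count * 1e9 / (gene_length * library_size)) / fpkm)
  expect_true(all(rel < 1e-12))
})

test_that("status thresholds are exactly the printed ones", {
  df <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    log2fc = c(1.2, 0.5, -1.5, 1.0, 2.0, 0),
    padj = c(0.04, 0.04, 0.01, 0.05, NA, 0.9))
  out <- deg_calls_from_table(df)
  expect_identical(out$status,
                   c("up", "ns", "down", "ns", "ns", "ns"))
})

test_that("identical count vectors in both groups are never DE", {
  counts <- tibble::tibble(gene_id = paste0("g", 1:20),
                           hybrid_1 = 10:29, hybrid_2 = 15:34,
                           maternal_1 = 10:29, maternal_2 = 15:34)
  groups <- c(hybrid_1 = "hybrid", hybrid_2 = "hybrid",
              maternal_1 = "maternal", maternal_2 = "maternal")
  out <- suppressMessages(call_degs(counts, groups))
  expect_true(all(out$status == "ns"))
  expect_true(all(abs(out$log2fc) < 1e-4, na.rm = TRUE))
})

test_that("flipping group labels negates every log2 fold change", {
  counts <- tibble::tibble(gene_id = paste0("g", 1:10),
                           a = c(200L, 5:13), b = c(180L, 6:14),
                           c = c(20L, 5:13), d = c(25L, 6:14))
  g1 <- c(a = "hybrid", b = "hybrid", c = "maternal", d = "maternal")
  g2 <- c(a = "maternal", b = "maternal", c = "hybrid", d = "hybrid")
  out1 <- suppressMessages(call_degs(counts, g1))
  out2 <- suppressMessages(call_degs(counts, g2))
  expect_equal(out1$log2fc, -out2$log2fc, tolerance = 1e-3)
})

test_that("all-zero genes are flagged and ns; single-replicate data uses the exact test", {
  counts <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                           h = c(0L, 100L, 1000L), m = c(0L, 10L, 1000L))
  out <- call_degs(counts, c(h = "hybrid", m = "maternal"))
  expect_identical(attr(out, "params")$method, "exact")
  expect_true(out$zero_expression[1])
  expect_identical(out$status[1], "ns")
  expect_identical(out$status[2], "up")
})

test_that("planted DEGs are recovered with correct direction", {
  run <- reference_run()
  truth <- run$sim$truth$deg_genes
  joined <- dplyr::inner_join(truth, tibble::as_tibble(run$degs),
                              by = "gene_id", suffix = c("_t", "_c"))
  planted <- dplyr::filter(joined, status_t != "ns")
  expect_gte(mean(planted$status_c == planted$status_t), 0.9)
})

test_that("shared genes partition by direction consistency", {
  degs <- tidyr::expand_grid(gene_id = paste0("g", 1:5),
                             tissue = c("pituitarium", "liver", "muscle")) |>
    dplyr::mutate(status = dplyr::case_when(
      gene_id == "g1" ~ "up",
      gene_id == "g2" ~ "down",
      gene_id == "g3" & tissue == "liver" ~ "down",
      gene_id == "g3" ~ "up",
      gene_id == "g4" & tissue == "muscle" ~ "ns",
      gene_id == "g4" ~ "up",
      .default = "ns"))
  out <- shared_gene_partition(degs)
  expect_identical(out$counts$n_shared, 3L)
  expect_identical(out$counts$n_all_up, 1L)
  expect_identical(out$counts$n_all_down, 1L)
  expect_identical(out$counts$n_inconsistent, 1L)
  expect_setequal(out$shared$gene_id, c("g1", "g2", "g3"))
  # disjoint DEG sets share nothing
  disjoint <- tibble::tibble(
    gene_id = c("a", "b"), tissue = c("t1", "t2"), status = "up")
  expect_identical(shared_gene_partition(disjoint)$counts$n_shared, 0L)
})

test_that("reference Venn sets are disjoint and conserve totals", {
  orth <- tibble::tibble(paternal_gene = c("a", "b", "d"),
                         maternal_gene = c("A", "B", "D"))
  out <- reference_venn(c("a", "b"), c("B", "C"), orth)
  expect_identical(out$counts$n_overlap, 1L)          # b <-> B
  expect_identical(out$unique_paternal, "a")
  expect_identical(out$unique_maternal, "C")
  expect_identical(out$counts$n_overlap + out$counts$n_unique_paternal, 2L)
  # identical sets through the map: all overlap
  same <- reference_venn(c("a", "b"), c("A", "B"), orth)
  expect_identical(same$counts$n_unique_paternal, 0L)
  expect_identical(same$counts$n_unique_maternal, 0L)
})

test_that("reference Venn conserves totals on simulated truth", {
  sim <- small_sim()
  orth <- sim$truth$ortholog_pairs
  pat_de <- sim$truth$deg_genes$gene_id[sim$truth$deg_genes$status != "ns"]
  # maternal-side DEG set: same genes through the map, minus one, plus none
  mat_de <- sub("^g", "m", pat_de[-1])
  out <- reference_venn(pat_de, mat_de, orth)
  expect_identical(out$counts$n_overlap + out$counts$n_unique_paternal,
                   length(pat_de))
  expect_identical(out$counts$n_overlap + out$counts$n_unique_maternal,
                   length(mat_de))
})
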