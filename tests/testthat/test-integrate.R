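test_that("expression bins follow the printed half-open boundaries", {
  expr <- tibble::tibble(gene_id = paste0("g", 1:6),
                         fpkm = c(0.5, 1, 10, 100, 150, 0))
  out <- bin_expression(expr)
  expect_identical(as.character(out$bin),
                   c("non", "non", "low", "middle", "high", "non"))
})

test_that("bins partition every non-negative value", {
  set.seed(90)
  expr <- tibble::tibble(gene_id = paste0("g", 1:500),
                         fpkm = c(0, 1, 10, 100,
                                  10^runif(496, -3, 4)))
  out <- bin_expression(expr)
  expect_false(anyNA(out$bin))
  expect_error(bin_expression(tibble::tibble(gene_id = "g", fpkm = -1)),
               class = "hybridscope_config_error")
})

test_that("perfect anti-ordering gives rho = -1; constant levels are undefined", {
  expr <- tibble::tibble(gene_id = paste0("g", 1:20),
                         fpkm = c(0.5, 5, 50, 500)[rep(1:4, each = 5)] *
                           (1 + 0.01 * (1:20)))
  levels <- tibble::tibble(gene_id = paste0("g", 1:20),
                           region = "gene_body", context = "CG",
                           level = 1 - rank(expr$fpkm) / 21)
  out <- methylation_by_bin(expr, levels)
  expect_equal(out$correlation$rho, -1)
  # constant methylation: correlation reported absent
  const <- dplyr::mutate(levels, level = 0.5)
  out2 <- methylation_by_bin(expr, const)
  expect_false(out2$correlation$defined)
  expect_true(is.na(out2$correlation$rho))
})

test_that("planted gene-body coupling is recovered per region with correct sign", {
  set.seed(91)
  n <- 60
  expr <- tibble::tibble(gene_id = sprintf("g%03d", 1:n),
                         fpkm = 10^runif(n, -1, 3))
  # negative coupling in the gene body, none upstream
  levels <- dplyr::bind_rows(
    tibble::tibble(gene_id = expr$gene_id, region = "gene_body",
                   context = "CG",
                   level = plogis(2 - 0.8 * log10(expr$fpkm) +
                                    rnorm(n, 0, 0.3))),
    tibble::tibble(gene_id = expr$gene_id, region = "upstream2kb",
                   context = "CG", level = runif(n, 0.3, 0.7)))
  out <- methylation_by_bin(expr, levels)
  body <- out$correlation[out$correlation$region == "gene_body", ]
  up <- out$correlation[out$correlation$region == "upstream2kb", ]
  expect_lt(body$rho, -0.5)
  expect_lt(body$p, 0.01)
  expect_gt(up$p, 0.01)
  # per-bin mean gene-body methylation decreases with expression class
  prof <- dplyr::arrange(
    dplyr::filter(out$profile, region == "gene_body"), bin)
  expect_true(all(diff(prof$mean_level) < 0))
})

test_that("quadrants label the DEG/DMG intersection and exclude single-omics genes", {
  degs <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                         status = c("up", "down", "up"))
  dmgs <- tibble::tibble(
    gene_id = c("g1", "g2", "g4"),
    region = "gene_body", context = "CG", n_sites = 5L,
    delta = c(0.5, -0.4, 0.3), q = 0.01,
    status = c("hyper", "hypo", "hyper"))
  out <- common_genes(degs, dmgs)
  expect_setequal(out$gene_id, c("g1", "g2"))  # g3 DE-only, g4 DM-only
  expect_identical(out$quadrant[out$gene_id == "g1"], "E+M+")
  expect_identical(out$quadrant[out$gene_id == "g2"], "E-M-")
})

test_that("quadrant labels are a bijection with direction pairs", {
  grid <- tidyr::expand_grid(deg = c("up", "down"),
                             dmg = c("hyper", "hypo"))
  degs <- tibble::tibble(gene_id = paste0("g", 1:4), status = grid$deg)
  dmgs <- tibble::tibble(gene_id = paste0("g", 1:4), region = "gene_body",
                         context = "CG", n_sites = 5L,
                         delta = ifelse(grid$dmg == "hyper", 0.4, -0.4),
                         q = 0.01, status = grid$dmg)
  out <- common_genes(degs, dmgs)
  expect_identical(sort(out$quadrant),
                   sort(c("E+M+", "E+M-", "E-M+", "E-M-")))
})

test_that("opposite DMRs in one region are flagged multi-hit with a weighted direction", {
  degs <- tibble::tibble(gene_id = "g1", status = "up")
  dmgs <- tibble::tibble(
    gene_id = "g1", region = "gene_body", context = "CG",
    n_sites = c(10L, 2L), delta = c(0.5, -0.3), q = 0.01,
    status = c("hyper", "hypo"))
  out <- common_genes(degs, dmgs)
  expect_identical(nrow(out), 2L)           # one record per DMR
  expect_true(all(out$multi_hit))
  expect_identical(unique(out$region_direction), "hyper")  # 10*0.5 > 2*0.3
})
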