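test_that("methylcytosine calling tests counts against the conversion error", {
  sites <- toy_sites("chr1", c(10, 20, 30), "CG",
                     m = c(10, 0, 1), u = c(0, 50, 99))
  out <- call_methylcytosines(sites, conversion_error = 0.01)
  # all 10 reads methylated at error 0.01: p = 0.01^10
  expect_equal(out$p[1], 1e-20, tolerance = 1e-8)
  expect_true(out$methylated[1])
  # zero methylated reads: p = 1
  expect_identical(out$p[2], 1)
  expect_false(out$methylated[2])
  # 1 of 100 at error 0.01: survival p ~ 0.634
  expect_equal(out$p[3],
               stats::pbinom(0, 100, 0.01, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(out$p[3], 0.6339677, tolerance = 1e-6)
  expect_false(out$methylated[3])
})

test_that("uncovered sites are flagged unevaluated", {
  sites <- toy_sites("chr1", 10, "CG", m = 0, u = 0)
  out <- call_methylcytosines(sites)
  expect_false(out$evaluated)
  expect_true(is.na(out$p))
  expect_error(call_methylcytosines(sites, conversion_error = 0),
               class = "hybridscope_config_error")
})

test_that("levels pool counts coverage-weighted and skip empty scopes", {
  sites <- toy_sites("chr1", c(10, 20), "CG", m = c(3, 1), u = c(1, 3))
  lv <- methylation_levels(sites)
  expect_identical(lv$level[lv$context == "CG"], 0.5)
  expect_identical(lv$level[lv$context == "allC"], 0.5)
  # fully methylated sites give level 1 everywhere
  all_m <- toy_sites("chr1", c(10, 20), c("CG", "CHH"),
                     m = c(5, 7), u = c(0, 0))
  expect_true(all(methylation_levels(all_m)$level == 1))
  # a context with no covered site yields no row rather than zero
  zero_cov <- toy_sites("chr1", c(10, 20), c("CG", "CHH"),
                        m = c(5, 0), u = c(0, 0))
  lv2 <- methylation_levels(zero_cov)
  expect_false("CHH" %in% lv2$context)
})

test_that("window Fisher p equals hypergeometric enumeration", {
  a <- toy_sites("chr1", seq(10, 90, by = 20), "CG",
                 m = c(9, 9, 9, 9, 9), u = c(1, 1, 1, 1, 1))
  b <- toy_sites("chr1", seq(10, 90, by = 20), "CG",
                 m = c(4, 4, 4, 4, 4), u = c(6, 6, 6, 6, 6))
  out <- call_dmrs(a, b, contexts = "CG")
  expect_identical(nrow(dplyr::filter(tibble::as_tibble(out), tested)), 1L)
  # pooled table is 45/5 vs 20/30
  expect_equal(out$p[out$tested], fisher_oracle(45, 5, 20, 30),
               tolerance = 1e-12)
  expect_equal(out$p[out$tested], 1.958312e-07, tolerance = 1e-6)
  expect_identical(out$status[out$tested], "hyper")
  expect_equal(out$delta[out$tested], 0.5)
})

test_that("Fisher p agrees with enumeration across random pooled tables", {
  set.seed(77)
  for (i in 1:60) {
    n1 <- sample(1:100, 1)
    n2 <- sample(1:100, 1)
    ma <- rbinom(1, n1, runif(1))
    mb <- rbinom(1, n2, runif(1))
    got <- stats::fisher.test(matrix(c(ma, n1 - ma, mb, n2 - mb), 2,
                                     byrow = TRUE))$p.value
    expect_equal(got, fisher_oracle(ma, n1 - ma, mb, n2 - mb),
                 tolerance = 1e-12)
  }
})

test_that("context eligibility matches the printed site and delta minimums", {
  crit <- dmr_criteria()
  expect_identical(crit$min_sites[crit$context == "CG"], 5L)
  expect_identical(crit$min_delta[crit$context == "CHH"], 0.15)

  # 4 CG sites in a window: ineligible, no call
  a4 <- toy_sites("chr1", c(10, 20, 30, 40), "CG", m = 10, u = 0)
  b4 <- toy_sites("chr1", c(10, 20, 30, 40), "CG", m = 0, u = 10)
  out4 <- call_dmrs(a4, b4, contexts = "CG")
  expect_false(any(out4$tested))
  expect_true(all(out4$status == "none"))

  # CHH: 15 sites with delta exactly 0.15 is callable; a CG window with
  # delta 0.20 is not (gate 0.25)
  pos <- seq(5, 145, by = 10)
  a_chh <- toy_sites("chr1", pos, "CHH", m = 8, u = 12)   # level 0.40
  b_chh <- toy_sites("chr1", pos, "CHH", m = 5, u = 15)   # level 0.25
  out_chh <- call_dmrs(a_chh, b_chh, contexts = "CHH")
  expect_identical(out_chh$status[out_chh$tested], "hyper")
  expect_equal(out_chh$delta[out_chh$tested], 0.15)

  pos5 <- seq(5, 45, by = 10)
  a_cg <- toy_sites("chr1", pos5, "CG", m = 12, u = 8)    # level 0.60
  b_cg <- toy_sites("chr1", pos5, "CG", m = 8, u = 12)    # level 0.40
  out_cg <- call_dmrs(a_cg, b_cg, contexts = "CG")
  expect_true(all(out_cg$status == "none"))
  expect_equal(out_cg$delta[out_cg$tested], 0.2)
})

test_that("sites below the coverage floor are excluded in either group", {
  a <- toy_sites("chr1", c(10, 20), "CG", m = c(3, 10), u = c(0, 0))
  b <- toy_sites("chr1", c(10, 20), "CG", m = c(0, 0), u = c(10, 10))
  out <- call_dmrs(a, b, contexts = "CG")
  expect_identical(out$n_sites, 1L)  # coverage-3 site dropped
})

test_that("swapping groups negates delta and mirrors the call", {
  sim <- small_sim()
  fwd <- call_dmrs(sim$tables$meth$hybrid, sim$tables$meth$maternal)
  rev <- call_dmrs(sim$tables$meth$maternal, sim$tables$meth$hybrid)
  expect_equal(fwd$delta, -rev$delta)
  expect_equal(fwd$p, rev$p)
  map <- c(hyper = "hypo", hypo = "hyper", none = "none")
  expect_identical(unname(map[fwd$status]), rev$status)
})

test_that("window levels equal the pooled methylation level of the window", {
  a <- toy_sites("chr1", c(10, 60, 110, 150, 190), "CG",
                 m = c(5, 6, 7, 8, 9), u = c(5, 4, 3, 2, 1))
  b <- toy_sites("chr1", c(10, 60, 110, 150, 190), "CG",
                 m = 5, u = 5)
  dmr <- call_dmrs(a, b, contexts = "CG")
  lv <- methylation_levels(a)
  expect_equal(dmr$level_a[dmr$tested],
               lv$level[lv$context == "CG"])
})

test_that("site-level differential calls follow the same gates", {
  a <- toy_sites("chr1", c(10, 20, 30), "CG",
                 m = c(20, 5, 2), u = c(0, 5, 1))
  b <- toy_sites("chr1", c(10, 20, 30), "CG",
                 m = c(0, 5, 0), u = c(20, 5, 3))
  out <- call_dmcs(a, b)
  # site 30 has coverage 3 in both groups: excluded
  expect_identical(nrow(out), 2L)
  s1 <- out[out$pos == 10, ]
  expect_identical(s1$status, "hyper")
  expect_equal(s1$delta, 1)
  expect_equal(s1$p, fisher_oracle(20, 0, 0, 20), tolerance = 1e-12)
  # identical counts: p = 1, no call
  s2 <- out[out$pos == 20, ]
  expect_identical(s2$p, 1)
  expect_identical(s2$status, "none")
})

test_that("DMR-gene association respects region boundaries", {
  gm <- toy_gene_models()
  # gA: body 100-400 (+); upstream 1-99 truncated; gB: body 350-700 (-),
  # upstream 701-2700
  calls <- tibble::tibble(
    chrom = "chr1",
    start = c(200L, 700L, 3200L),
    end = c(400L, 900L, 3400L),
    context = "CG", n_sites = 5L, delta = 0.5, q = 0.01,
    tested = TRUE, status = "hyper")
  out <- annotate_dmr_genes(calls, gm)
  in_body <- out[out$start == 200 & out$gene_id == "gA", ]
  expect_identical(unique(in_body$region), "gene_body")
  # window [700, 900) touches gB's upstream flank (701-2700) by overlap
  up <- out[out$start == 700 & out$gene_id == "gB", ]
  expect_true("upstream2kb" %in% up$region)
  # a window beyond the 2 kb flank is not associated
  expect_false(any(out$start == 3200))
})
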