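test_that("coverage filter is inclusive at the threshold and idempotent", {
  s <- make_sample("d", pos = c(10L, 20L, 30L), frac = c(0.5, 0.5, 0.5),
                   depth = c(5L, 4L, 30L))
  f5 <- filter_by_coverage(s, 5L)
  expect_equal(f5$pos, c(10L, 30L))            # depth 5 kept, 4 dropped
  expect_equal(as.data.frame(filter_by_coverage(f5, 5L)), as.data.frame(f5))
  expect_equal(as.data.frame(filter_by_coverage(s, 0L)), as.data.frame(s))
})

test_that("common-CpG intersection matches set logic", {
  a <- make_sample("a", pos = c(100L, 200L), frac = c(0.5, 0.5))
  b <- make_sample("b", pos = c(200L, 300L), frac = c(0.2, 0.8))
  got <- intersect_common_cpgs(list(a, b))
  expect_equal(got$positions$pos, 200L)
  expect_equal(unname(got$fractions[1, ]), c(0.5, 0.2))

  same <- intersect_common_cpgs(list(a, a))
  expect_equal(same$positions$pos, c(100L, 200L))

  c_s <- make_sample("c", pos = 999L, frac = 0.5)
  expect_warning(empty <- intersect_common_cpgs(list(a, c_s)), "no CpG")
  expect_equal(nrow(empty$positions), 0L)
  expect_error(intersect_common_cpgs(list(a)), "at least 2")
})

test_that("intersection equals a brute-force recount on simulated samples", {
  sim <- simulate_all(tiny_sim_config(seed = 14L, depth_mean = 8))
  trio <- lapply(sim$methylomes[1:3], filter_by_coverage, 5L)
  got <- intersect_common_cpgs(trio)
  keys <- lapply(trio, function(s) paste(s$chrom, s$pos))
  brute <- Reduce(intersect, keys)
  expect_equal(nrow(got$positions), length(brute))
  expect_setequal(paste(got$positions$chrom, got$positions$pos), brute)
})

test_that("methylation bins use a closed first bin and conserve totals", {
  expect_equal(unname(bin_values(80)["76-100%"]), 1L)
  expect_equal(unname(bin_values(25)["0-25%"]), 1L)    # boundary: first bin
  b <- bin_values(c(10, 30, 60, 90))
  expect_true(all(b == 1L))
  expect_equal(names(b), c("0-25%", "26-50%", "51-75%", "76-100%"))
  set.seed(1)
  v <- runif(500, 0, 100)
  expect_equal(sum(bin_values(v)), 500L)
  expect_error(bin_values(c(50, 101)), "outside")
  expect_error(bin_values(-1), "outside")
})

test_that("promoter means are unweighted and missing promoters flagged", {
  catalog <- feature_catalog(data.frame(
    chrom = "chr1", start = c(1000, 9000), end = c(3000, 11000),
    category = "promoter", gene_id = c("GA", "GB"), strand = c("+", "+")))
  s <- make_sample("p", pos = c(1500L, 2000L, 2500L), frac = c(0.8, 0.9, 1.0),
                   depth = c(10L, 100L, 10L))   # coverage must not weight
  pm <- promoter_mean_methylation(s, catalog)
  expect_equal(pm[pm$gene_id == "GA", ]$mean_meth, 90)
  expect_true(is.na(pm[pm$gene_id == "GB", ]$mean_meth))
  expect_equal(pm[pm$gene_id == "GB", ]$n_cpgs, 0L)
})

test_that("minus-strand promoters span TSS-500 to TSS+1500", {
  tss <- 10000L
  w <- promoter_window(tss, "-")
  catalog <- feature_catalog(data.frame(
    chrom = "chr1", start = w$start, end = w$end,
    category = "promoter", gene_id = "GM", strand = "-"))
  inside <- c(tss - 400L, tss + 1400L)
  outside <- c(tss - 600L, tss + 1600L)
  s <- make_sample("m", pos = sort(c(inside, outside)), frac = 1)
  pm <- promoter_mean_methylation(s, catalog)
  expect_equal(pm$n_cpgs, 2L)   # only the two inside CpGs
})

test_that("pearson matrix: identities, hand formula, undefined columns", {
  set.seed(3)
  x <- rnorm(5)
  m <- cbind(a = x, b = -(x - mean(x)) + 2, c = rnorm(5))
  R <- pearson_matrix(m)
  expect_equal(diag(R), c(a = 1, b = 1, c = 1))
  expect_equal(R["a", "b"], -1)
  # hand-evaluated Pearson formula for the a-c pair
  hand <- sum((x - mean(x)) * (m[, 3] - mean(m[, 3]))) /
    sqrt(sum((x - mean(x))^2) * sum((m[, 3] - mean(m[, 3]))^2))
  expect_equal(R["a", "c"], hand)
  # affine rescaling with positive scale leaves R unchanged
  R2 <- pearson_matrix(cbind(m[, 1] * 3 + 7, m[, 2], m[, 3]))
  expect_equal(unname(R2), unname(R))
  Rz <- pearson_matrix(cbind(k = rep(1, 5), a = x))
  expect_true(is.na(Rz["k", "a"]))
  expect_true(is.na(Rz["k", "k"]))
})

test_that("methylation-expression strata: tests, skips and separation", {
  pm <- data.frame(gene_id = paste0("G", 1:9),
                   mean_meth = c(10, 12, 15, 60, 62, 65, 90, 95, 99),
                   n_cpgs = 5L)
  fpkm <- stats::setNames(c(5, 6, 7, 5, 6, 7, 1, 1, 2), pm$gene_id)
  st <- methylation_expression_strata(pm, fpkm)
  # identical FPKM multisets in bins 1 and 3 -> t = 0, p = 1
  row <- st$tests[st$tests$bin1 == "0-25%" & st$tests$bin2 == "51-75%", ]
  expect_equal(row$p_value, 1)
  expect_equal(row$t, 0)
  # empty bin tests are skipped and flagged
  expect_true(all(st$tests$skipped[st$tests$bin1 == "26-50%" |
                                     st$tests$bin2 == "26-50%"]))
  expect_equal(st$summary$n, c(3L, 0L, 3L, 3L))

  set.seed(99)
  pm2 <- data.frame(gene_id = paste0("H", 1:100),
                    mean_meth = c(runif(50, 0, 20), runif(50, 80, 100)))
  fpkm2 <- stats::setNames(c(rnorm(50, 100, 1), rnorm(50, 1, 1)), pm2$gene_id)
  st2 <- methylation_expression_strata(pm2, fpkm2)
  p <- st2$tests[st2$tests$bin1 == "0-25%" & st2$tests$bin2 == "76-100%", ]$p_value
  expect_lt(p, 1e-10)
})

test_that("simulated promoter methylation is inversely coupled to expression", {
  sim <- simulate_all(sim_config(seed = 13L))
  pipe <- pipeline_config()
  ctrl <- filter_by_coverage(sim$methylomes$ctrl_1, pipe$min_depth)
  pm <- promoter_mean_methylation(ctrl, sim$genome$catalog)
  fpkm <- compute_fpkm(sim$expression$counts, sim$expression$lengths)
  fv <- rowMeans(fpkm[, grep("^ectrl", colnames(fpkm)), drop = FALSE])
  st <- methylation_expression_strata(pm, fv)
  expect_true(all(diff(st$summary$mean_fpkm) < 0))   # strictly decreasing
  merged <- pm[!is.na(pm$mean_meth), ]
  rho <- stats::cor(merged$mean_meth, fv[merged$gene_id], method = "spearman")
  expect_lt(rho, 0)
})
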