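test_that("control averaging is unweighted and restricted to shared sites", {
  a <- make_sample("a", pos = c(100L, 200L), frac = c(0.8, 0.5), depth = 10L)
  b <- make_sample("b", pos = c(100L, 200L), frac = c(0.9, 0.5), depth = 10L)
  prof <- average_controls(list(a, b))
  expect_equal(prof$sites$mean_fraction, c(0.85, 0.5))
  expect_equal(prof$sites$n_controls_covered, c(2L, 2L))

  # a site under the depth filter in one of the controls is excluded
  c_s <- make_sample("c", pos = c(100L, 200L), frac = c(0.8, 0.5),
                     depth = c(10L, 4L))
  prof2 <- average_controls(list(a, b, c_s))
  expect_equal(prof2$sites$pos, 100L)

  single <- average_controls(list(a))
  expect_equal(single$sites$mean_fraction, c(0.8, 0.5))
  expect_error(average_controls(list(make_sample("x", 1L, 0.5, 3L))),
               "no CpG site|no sites")
})

test_that("DMC calling applies the inclusive 10-point threshold", {
  ctrl1 <- make_sample("c1", pos = c(10L, 20L, 30L), frac = c(0.80, 0.50, 0.70))
  ctrl2 <- make_sample("c2", pos = c(10L, 20L, 30L), frac = c(0.80, 0.50, 0.70))
  prof <- average_controls(list(ctrl1, ctrl2))
  tumor <- make_sample("t", pos = c(10L, 20L, 30L), frac = c(0.65, 0.55, 0.80))
  dmcs <- call_dmcs(tumor, prof)
  expect_equal(dmcs$pos, c(10L, 30L))          # +5 points is not a DMC
  expect_equal(dmcs$delta, c(-15, 10))          # exactly +10 is (inclusive)
  expect_equal(dmcs$direction, c("hypo", "hyper"))
})

test_that("segmentation reproduces the hand-traced examples", {
  cfg <- pipeline_config()
  dmcs <- data.table::data.table(
    chrom = "chr1", pos = c(100L, 150L, 220L, 400L),
    delta = c(-12, -15, -11, 20),
    direction = c("hypo", "hypo", "hypo", "hyper"),
    tumor_fraction = 0.5, profile_row = 1:4)
  cand <- segment_dmrs(dmcs, cfg)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, 100)
  expect_equal(cand$end, 221)
  expect_equal(cand$n_cpgs, 3L)
  expect_equal(cand$mean_delta, mean(c(-12, -15, -11)))
  expect_equal(cand$direction, "hypo")

  # gaps of exactly 101 bp break the run under the <= 100 rule
  gap101 <- data.table::copy(dmcs)[1:3][, pos := c(100L, 201L, 302L)]
  expect_equal(nrow(segment_dmrs(gap101, cfg)), 0L)
  # a gap of exactly 100 does not
  gap100 <- data.table::copy(dmcs)[1:3][, pos := c(100L, 200L, 300L)]
  expect_equal(nrow(segment_dmrs(gap100, cfg)), 1L)

  # direction flips split runs below the 3-DMC minimum
  flip <- data.table::copy(dmcs)[1:3][, `:=`(pos = c(100L, 150L, 200L),
                                             delta = c(-12, 15, -11),
                                             direction = c("hypo", "hyper", "hypo"))]
  expect_equal(nrow(segment_dmrs(flip, cfg)), 0L)

  # chromosome changes terminate runs even at small coordinate gaps
  cross <- data.table::copy(dmcs)[1:4][, `:=`(
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    pos = c(100L, 150L, 160L, 210L),
    delta = c(-12, -15, -11, -20),
    direction = "hypo")]
  expect_equal(nrow(segment_dmrs(cross, cfg)), 0L)
})

test_that("region MWU test matches the documented exact cases", {
  p <- mwu_region_test(c(0.10, 0.20, 0.15),
                       matrix(c(0.80, 0.85, 0.90), ncol = 1))
  expect_equal(p, 0.1, tolerance = 1e-12)
  expect_equal(mwu_region_test(c(0.1, 0.2, 0.3),
                               matrix(c(0.1, 0.2, 0.3), ncol = 1)), 1)
  expect_error(mwu_region_test(numeric(), matrix(1)), "non-empty")
})

test_that("a planted region is recovered; alpha = 0 empties the output", {
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 1.5e5, n_genes = 10L,
                    n_planted_hypo = 1L, n_planted_hyper = 0L,
                    planted_effect = 0.3, planted_width_cpgs = 6L,
                    n_tumors = 1L, coupled_gene_fraction = 0,
                    recurrence_schedule = list(1L), seed = 17L)
  sim <- simulate_all(cfg)
  controls <- sim$methylomes[grep("^ctrl", names(sim$methylomes))]
  dmrs <- call_dmrs(sim$methylomes$tumor_1, controls)
  planted <- sim$truth$planted_dmrs
  hit <- any(dmrs$direction == "hypo" & dmrs$chrom == planted$chrom &
               dmrs$start < planted$end & dmrs$end > planted$start)
  expect_true(hit)
  expect_true(all(dmrs$p_value < 0.05))
  expect_true(all(abs(dmrs$mean_delta) >= 10))

  none <- call_dmrs(sim$methylomes$tumor_1, controls,
                    pipeline_config(alpha = 0))
  expect_equal(nrow(none), 0L)
})

test_that("reported DMRs partition: no overlaps within a tumor", {
  sim <- simulate_all(tiny_sim_config(seed = 19L))
  controls <- sim$methylomes[grep("^ctrl", names(sim$methylomes))]
  prof <- average_controls(controls, pipeline_config())
  for (tm in c("tumor_1", "tumor_4")) {
    d <- call_dmrs_profiled(sim$methylomes[[tm]], prof, pipeline_config())
    if (nrow(d) > 1L) {
      d <- d[order(d$chrom, d$start), ]
      same <- d$chrom[-1] == d$chrom[-nrow(d)]
      expect_true(all(d$start[-1][same] >= d$end[-nrow(d)][same]))
    }
  }
})

test_that("thresholds act monotonically on DMCs and candidates", {
  sim <- simulate_all(tiny_sim_config(seed = 23L))
  controls <- sim$methylomes[grep("^ctrl", names(sim$methylomes))]
  prof <- average_controls(controls, pipeline_config())
  tumor <- sim$methylomes$tumor_2

  n_dmcs <- vapply(c(5, 10, 15, 20, 30), function(md) {
    nrow(call_dmcs(tumor, prof, pipeline_config(dmc_min_delta = md)))
  }, numeric(1))
  expect_true(all(diff(n_dmcs) <= 0))

  dmcs <- call_dmcs(tumor, prof, pipeline_config())
  n_cand <- vapply(c(20, 50, 100, 200, 500), function(gap) {
    nrow(segment_dmrs(dmcs, pipeline_config(dmr_max_gap = gap)))
  }, numeric(1))
  expect_true(all(diff(n_cand) >= 0))
})

test_that("BH correction across candidates never reports more than raw alpha", {
  sim <- simulate_all(tiny_sim_config(seed = 29L))
  controls <- sim$methylomes[grep("^ctrl", names(sim$methylomes))]
  raw <- call_dmrs(sim$methylomes$tumor_1, controls, pipeline_config())
  fdr <- call_dmrs(sim$methylomes$tumor_1, controls, pipeline_config(fdr = TRUE))
  expect_lte(nrow(fdr), nrow(raw))
  if (nrow(fdr)) expect_true(all(fdr$p_adjusted < 0.05))
})
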