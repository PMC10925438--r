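test_that("promoter windows follow the strand-oriented -1500/+500 rule", {
  w <- promoter_window(50000L, "+")
  expect_equal(w$start, 48500)
  expect_equal(w$end, 50500)
  wm <- promoter_window(50000L, "-")
  expect_equal(wm$end - wm$start, 2000)
  expect_equal(wm$start, 49501)   # TSS - 500 + 1 in half-open coordinates
  expect_equal(wm$end, 51501)
  expect_error(promoter_window(1, "x"), "strand")
})

test_that("a 1-chromosome 10-gene genome has ten 2000 bp promoters", {
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 1.5e5, n_genes = 10L,
                    n_planted_hypo = 2L, n_planted_hyper = 1L,
                    coupled_gene_fraction = 0, seed = 5L)
  genome <- generate_genome(cfg)
  prom <- genome$catalog[genome$catalog$category == "promoter", ]
  expect_equal(nrow(prom), 10L)
  expect_true(all(prom$end - prom$start == 2000))
  expect_true(all(prom$strand %in% c("+", "-")))
  # CpGs strictly increasing with roughly the configured spacing
  expect_true(all(diff(genome$cpgs$pos) > 0))
  expect_equal(mean(diff(genome$cpgs$pos)), cfg$cpg_spacing_mean,
               tolerance = 0.1)
})

test_that("the generator is deterministic and sizing errors are explicit", {
  cfg <- tiny_sim_config(seed = 11L)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_equal(as.data.frame(g1$cpgs), as.data.frame(g2$cpgs))
  expect_equal(as.data.frame(g1$catalog), as.data.frame(g2$catalog))
  expect_error(
    generate_genome(sim_config(n_chromosomes = 1L, chrom_length = 5e4,
                               n_genes = 40L, seed = 1L)),
    "too short")
})

test_that("same seed reproduces methylomes and expression bit for bit", {
  cfg <- tiny_sim_config(seed = 2L)
  a <- simulate_all(cfg)
  b <- simulate_all(cfg)
  for (nm in names(a$methylomes))
    expect_equal(as.data.frame(a$methylomes[[nm]]),
                 as.data.frame(b$methylomes[[nm]]))
  expect_identical(a$expression$counts, b$expression$counts)
  # and the serialized form is byte-identical
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_bismark_coverage(a$methylomes[[1]], fa)
  write_bismark_coverage(b$methylomes[[1]], fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("planted shifts land at the configured effect; non-carriers do not", {
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 4e5, n_genes = 30L,
                    n_planted_hypo = 10L, n_planted_hyper = 0L,
                    planted_effect = 0.3, planted_width_cpgs = 8L,
                    n_tumors = 2L, coupled_gene_fraction = 0,
                    recurrence_schedule = rep(list(1L), 10L), seed = 8L)
  sim <- simulate_all(cfg)
  idx <- unlist(sim$truth$planted_dmrs$cpg_idx)
  ctrl_mean <- Reduce(`+`, lapply(
    sim$methylomes[grep("^ctrl", names(sim$methylomes))],
    function(s) s$count_meth[idx] / s$count_total[idx])) / cfg$n_controls
  t1 <- sim$methylomes$tumor_1
  t2 <- sim$methylomes$tumor_2
  d_carrier <- mean(t1$count_meth[idx] / t1$count_total[idx] - ctrl_mean)
  d_noncarr <- mean(t2$count_meth[idx] / t2$count_total[idx] - ctrl_mean)
  # binomial standard error at depth ~30 over the pooled planted CpGs
  se <- sqrt(0.25 / 30 / length(idx) * (1 + 1 / cfg$n_controls))
  expect_lt(abs(d_carrier + 0.3), 3 * se + 0.01)
  expect_lt(abs(d_noncarr), 3 * se + 3 * cfg$tumor_noise_sd / sqrt(length(idx)) + 0.01)
})

test_that("truth/position mismatches are consistency errors", {
  cfg <- tiny_sim_config(seed = 4L)
  genome <- generate_genome(cfg)
  truth <- plant_truth(cfg, genome)
  truth$planted_dmrs$start[1] <- truth$planted_dmrs$start[1] + 1
  expect_error(simulate_methylomes(cfg, genome, truth), "mismatch")
})

test_that("controls are near-identical: pairwise Pearson at least 0.95", {
  for (s in c(1L, 2L)) {
    sim <- simulate_all(sim_config(seed = s))
    controls <- sim$methylomes[grep("^ctrl", names(sim$methylomes))]
    cc <- intersect_common_cpgs(lapply(controls, filter_by_coverage, 5L))
    expect_gte(min(pearson_matrix(cc$fractions)), 0.95)
  }
})

test_that("carrier sets in the truth equal the tumors that were shifted", {
  cfg <- tiny_sim_config(seed = 6L)
  sim <- simulate_all(cfg)
  pd <- sim$truth$planted_dmrs
  ctrl_mean <- Reduce(`+`, lapply(
    sim$methylomes[grep("^ctrl", names(sim$methylomes))],
    meth_fraction)) / cfg$n_controls
  for (i in seq_len(nrow(pd))) {
    idx <- pd$cpg_idx[[i]]
    sgn <- if (pd$direction[i] == "hypo") -1 else 1
    for (j in seq_len(cfg$n_tumors)) {
      tm <- sim$methylomes[[sprintf("tumor_%d", j)]]
      d <- mean(meth_fraction(tm)[idx] - ctrl_mean[idx])
      if (j %in% pd$carriers[[i]]) {
        expect_gt(sgn * d, pd$effect[i] / 2)   # clearly shifted
      } else {
        expect_lt(sgn * d, pd$effect[i] / 2)   # clearly not
      }
    }
  }
})

test_that("expression counts follow the coupled fold-change law", {
  # pooled over seeds to reach >= 100 coupled-gene replicates
  ratios_count <- c(); ratios_fpkm <- c()
  for (s in 1:13) {
    sim <- simulate_all(sim_config(seed = s))
    cg <- sim$truth$coupled_genes[sim$truth$coupled_genes$direction == "hypo", ]
    cts <- sim$expression$counts
    lib <- sim$expression$library_sizes
    fpkm <- compute_fpkm(cts, sim$expression$lengths)
    ect <- grep("^ectrl", colnames(cts), value = TRUE)
    norm <- sweep(cts, 2, lib / 1e6, "/")   # normalize by the library parameter
    for (i in seq_len(nrow(cg))) {
      carr <- paste0("etumor_", cg$expr_carriers[[i]])
      g <- cg$gene_id[i]
      ratios_count <- c(ratios_count, mean(norm[g, carr]) / mean(norm[g, ect]))
      ratios_fpkm <- c(ratios_fpkm, mean(fpkm[g, carr]) / mean(fpkm[g, ect]))
    }
  }
  expect_gte(length(ratios_count), 100L)
  fc <- 10
  se <- stats::sd(ratios_count) / sqrt(length(ratios_count))
  # library-parameter-normalized ratio is composition-free: matches the law
  expect_lt(abs(mean(ratios_count) - fc), 3 * se + 0.05 * fc)
  # realized-FPKM ratio carries composition bias; still clearly ~10-fold
  expect_gt(mean(ratios_fpkm), 0.6 * fc)
  expect_lt(mean(ratios_fpkm), 1.6 * fc)
})

test_that("non-coupled genes have fold change near 1 and the NB limit is Poisson", {
  cfg <- sim_config(seed = 21L, expression_dispersion = 1e-4)
  sim <- simulate_all(cfg)
  cts <- sim$expression$counts
  lib <- sim$expression$library_sizes
  lens <- sim$expression$lengths
  mu <- outer(sim$expression$mu_fpkm * lens[rownames(cts)] / 1000, lib / 1e6)
  ect <- grep("^ectrl", colnames(cts), value = TRUE)
  null_genes <- setdiff(rownames(cts), sim$truth$coupled_genes$gene_id)
  norm <- sweep(cts, 2, lib / 1e6, "/")
  rat <- rowMeans(norm[null_genes, -seq_along(ect)]) /
    rowMeans(norm[null_genes, ect])
  expect_lt(abs(median(rat) - 1), 0.1)
  # dispersion -> 0: variance/mean of standardized counts approaches 1
  z <- (cts[null_genes, ] - mu[null_genes, ]) / sqrt(mu[null_genes, ])
  expect_lt(abs(stats::var(as.vector(z)) - 1), 0.15)
})

test_that("recurrence schedules are validated and honored", {
  expect_error(sim_config(recurrence_schedule = list(1L)), "one entry per")
  cfg <- sim_config(n_chromosomes = 1L, chrom_length = 2e5, n_genes = 20L,
                    n_planted_hypo = 2L, n_planted_hyper = 1L,
                    coupled_gene_fraction = 0, n_tumors = 3L,
                    recurrence_schedule = list(c(1L, 3L), 2L, c(1L, 2L, 3L)),
                    seed = 9L)
  truth <- plant_truth(cfg, generate_genome(cfg))
  expect_equal(truth$planted_dmrs$carriers,
               list(c(1L, 3L), 2L, c(1L, 2L, 3L)))
  expect_error(sim_config(n_tumors = 2L, n_planted_hypo = 1L,
                          n_planted_hyper = 0L, coupled_gene_fraction = 0,
                          recurrence_schedule = list(5L)),
               "subsets of tumor indices")
})
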