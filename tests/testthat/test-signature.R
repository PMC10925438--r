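make_dmr <- function(chrom, start, end, direction) {
  data.table::data.table(chrom = chrom, start = start, end = end,
                         direction = direction, n_cpgs = 3L,
                         mean_delta = ifelse(direction == "hypo", -15, 15),
                         p_value = 0.01)
}

test_that("recurrence is base-pair depth merging; toy case by hand", {
  dmr_list <- list(t1 = make_dmr("chr1", 100, 300, "hypo"),
                   t2 = make_dmr("chr1", 250, 400, "hypo"),
                   t3 = make_dmr("chr1", 150, 350, "hypo"))
  core <- recurrent_dmrs(dmr_list, n_required = 3)
  expect_equal(nrow(core$regions), 1L)
  expect_equal(core$regions$start, 250)
  expect_equal(core$regions$end, 300)
  expect_equal(sort(unique(core$support$tumor)), c("t1", "t2", "t3"))

  # support in 6 of 7 with n_required = 7 is excluded
  seven <- c(lapply(1:6, function(i) make_dmr("chr1", 1000, 1200, "hypo")),
             list(make_dmr("chr1", 5000, 5100, "hypo")))
  expect_equal(nrow(recurrent_dmrs(seven, 7)$regions), 0L)
  expect_equal(nrow(recurrent_dmrs(seven, 6)$regions), 1L)

  # direction must match
  mixed <- list(t1 = make_dmr("chr1", 100, 300, "hypo"),
                t2 = make_dmr("chr1", 100, 300, "hypo"),
                t3 = make_dmr("chr1", 100, 300, "hyper"))
  expect_equal(nrow(recurrent_dmrs(mixed, 3)$regions), 0L)

  expect_error(recurrent_dmrs(dmr_list, 4), "exceeds")
})

test_that("recurrence equals per-base brute force on random toys", {
  set.seed(41)
  for (rep in 1:10) {
    k <- sample(3:5, 1)
    dmr_list <- lapply(seq_len(k), function(i) {
      n <- sample(1:4, 1)
      st <- sort(sample(seq(0, 9000, by = 10), n))
      w <- sample(seq(50, 800, by = 10), n, replace = TRUE)
      d <- make_dmr("chr1", st, pmin(st + w, 10000),
                    sample(c("hypo", "hyper"), 1))
      # enforce within-tumor disjointness as the caller guarantees
      keep <- c(TRUE, if (n > 1) d$start[-1] >= cummax(d$end[-n]) else NULL)
      d[keep]
    })
    n_req <- sample(2:k, 1)
    core <- recurrent_dmrs(dmr_list, n_req)
    for (dir in c("hypo", "hyper")) {
      got <- core$regions[core$regions$direction == dir, ]
      brute <- recurrence_brute_force(dmr_list, n_req, dir)
      expect_equal(nrow(got), nrow(brute))
      if (nrow(brute)) {
        expect_equal(got$start, brute$start)
        expect_equal(got$end, brute$end)
      }
    }
  }
})

test_that("signature size is monotone in n_required", {
  set.seed(43)
  dmr_list <- lapply(1:5, function(i) {
    st <- sort(sample(seq(0, 5000, by = 100), 8))
    make_dmr("chr1", st, st + 80, "hypo")
  })
  sizes <- vapply(1:5, function(k) nrow(recurrent_dmrs(dmr_list, k)$regions),
                  numeric(1))
  covered <- vapply(1:5, function(k) {
    r <- recurrent_dmrs(dmr_list, k)$regions
    if (nrow(r)) sum(r$end - r$start) else 0
  }, numeric(1))
  expect_true(all(diff(covered) <= 0))   # covered bases shrink as k grows
})

test_that("core expression signature applies per-tumor fold thresholds", {
  fc <- rbind(A = c(2.1, 2.5, 3.0),
              B = c(2.1, 1.9, 3.0),
              C = c(0.4, 0.45, 0.5),
              D = c(0.4, 0.6, 0.5))
  sig <- core_expression_signature(fc, fc_threshold = 2)
  expect_equal(sig$up, "A")
  expect_equal(sig$down, "C")
  expect_length(intersect(sig$up, sig$down), 0)

  # threshold monotonicity
  s15 <- core_expression_signature(fc, fc_threshold = 1.5)
  expect_true(all(sig$up %in% s15$up))
  expect_true(all(sig$down %in% s15$down))
  expect_error(core_expression_signature(fc, 2, n_required = 4), "exceeds")
})

test_that("promoter DMR frequency caps each tumor at one per direction", {
  catalog <- feature_catalog(data.frame(
    chrom = "chr1", start = c(1000, 9000), end = c(3000, 11000),
    category = "promoter", gene_id = c("GA", "GB"), strand = "+"))
  idx <- build_interval_index(catalog)
  # tumor 1: three hypo DMRs plus one hyper DMR in GA's promoter
  t1 <- rbind(make_dmr("chr1", c(1100, 1500, 2000), c(1200, 1600, 2100), "hypo"),
              make_dmr("chr1", 2500, 2600, "hyper"))
  # tumors 2..6: one hypo DMR each in GA's promoter
  rest <- lapply(2:6, function(i) make_dmr("chr1", 1400, 1450, "hypo"))
  ann <- lapply(c(list(t1), rest), annotate_dmrs, index = idx)
  names(ann) <- paste0("tumor_", 1:6)
  freq <- promoter_dmr_frequency(ann, catalog)
  ga <- freq[freq$gene_id == "GA", ]
  expect_equal(ga$hypo_count, 6L)    # tumor 1 contributes 1, not 3
  expect_equal(ga$hyper_count, 1L)   # directions tallied independently
  expect_equal(freq[freq$gene_id == "GB", ]$hypo_count, 0L)
})

test_that("integration joins methylation frequency with expression quorum", {
  freq <- data.table::data.table(
    gene_id = c("GA", "GB", "GC", "GD"),
    hypo_count = c(6L, 6L, 5L, 0L),
    hyper_count = c(0L, 0L, 0L, 7L))
  de_list <- lapply(1:10, function(i) {
    data.table::data.table(
      gene_id = c("GA", "GB", "GC", "GD"),
      fold_change = c(10, 1.05, 10, 0.08),
      p_value = c(1e-6, 0.8, 1e-6, 1e-6),
      significant = c(TRUE, FALSE, TRUE, TRUE))
  })
  out <- integrate_signatures(freq, de_list, pipeline_config())
  expect_equal(out$hypo_up$gene_id, "GA")     # GB: expression unchanged
  expect_equal(out$hyper_down$gene_id, "GD")  # GC: only 5 of 7 tumors
  expect_equal(out$hypo_up$n_tumors_up, 10L)

  # quorum configurable: demanding 11 of 10 tumors empties the list
  strict <- integrate_signatures(freq, de_list,
                                 pipeline_config(integration_expr_min_tumors = 11L))
  expect_equal(nrow(strict$hypo_up), 0L)
})
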