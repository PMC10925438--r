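#' Coverage filter
#'
#' Keeps only CpG records sequenced to at least `min_depth` reads (inclusive:
#' a site at exactly `min_depth` is retained). Order is preserved and the
#' operation is idempotent.
#'
#' @param sample a [methylome_sample()].
#' @param min_depth minimum total read count.
#' @return a filtered [methylome_sample()].
#' @export
filter_by_coverage <- function(sample, min_depth = 5L) {
  if (!is_count1(min_depth)) stopf("filter_by_coverage: min_depth must be a count")
  methylome_sample(attr(sample, "sample_id"),
                   sample[sample$count_total >= min_depth])
}

#' Intersect samples on commonly covered CpGs
#'
#' Restricts a set of (coverage-filtered) methylomes to the CpG positions
#' present in every sample and aligns their methylation fractions.
#'
#' @param samples list of two or more [methylome_sample()]s.
#' @return list with `positions` (data.table `chrom`, `pos`) and `fractions`
#'   (matrix, one column per sample, values in `[0, 1]`). An empty
#'   intersection is returned explicitly (zero rows) with a warning.
#' @export
intersect_common_cpgs <- function(samples) {
  if (length(samples) < 2L)
    stopf("intersect_common_cpgs: need at least 2 samples")
  ids <- vapply(samples, function(s) attr(s, "sample_id"), character(1))
  common <- samples[[1]][, .(chrom, pos)]
  for (s in samples[-1]) {
    common <- common[s[, .(chrom, pos)], on = c("chrom", "pos"), nomatch = NULL]
  }
  data.table::setorder(common, chrom, pos)
  if (nrow(common) == 0L) {
    warnf("intersect_common_cpgs: no CpG covered in all %d samples",
          length(samples))
    return(list(positions = common,
                fractions = matrix(numeric(), nrow = 0, ncol = length(samples),
                                   dimnames = list(NULL, ids))))
  }
  frac <- vapply(samples, function(s) {
    m <- s[common, on = c("chrom", "pos")]
    m$count_meth / m$count_total
  }, numeric(nrow(common)))
  frac <- matrix(frac, nrow = nrow(common), dimnames = list(NULL, ids))
  list(positions = common, fractions = frac)
}

#' Bin percent values into methylation categories
#'
#' Default bins are `[0,25]`, `(25,50]`, `(50,75]`, `(75,100]`, labeled
#' "0-25%", "26-50%", "51-75%", "76-100%". The first bin is closed on the
#' left so that 0 and 100 are both housed and the bins partition the range.
#'
#' @param values numeric vector of percentages within the edge range.
#' @param edges strictly increasing bin edges (percent).
#' @return named integer vector of per-bin counts (sums to `length(values)`).
#' @export
bin_values <- function(values, edges = c(0, 25, 50, 75, 100)) {
  if (length(edges) < 2 || is.unsorted(edges, strictly = TRUE))
    stopf("bin_values: edges must be strictly increasing")
  values <- values[!is.na(values)]
  if (length(values) && (any(values < edges[1]) || any(values > edges[length(edges)])))
    stopf("bin_values: values outside [%g, %g]", edges[1], edges[length(edges)])
  labs <- bin_labels(edges)
  b <- cut(values, breaks = edges, include.lowest = TRUE, labels = labs)
  tab <- table(b)
  stats::setNames(as.integer(tab), names(tab))
}

bin_labels <- function(edges) {
  k <- length(edges) - 1L
  labs <- character(k)
  labs[1] <- sprintf("%g-%g%%", edges[1], edges[2])
  if (k > 1)
    labs[2:k] <- sprintf("%g-%g%%", edges[2:k] + 1, edges[3:(k + 1)])
  labs
}

#' Mean promoter methylation per gene
#'
#' Unweighted mean of the methylation percentages of all covered CpGs inside
#' each promoter interval of the catalog. Genes without a single covered CpG
#' are reported with `NA` (missing) so they can be excluded from bin counts.
#'
#' @param sample a coverage-filtered [methylome_sample()].
#' @param catalog a [feature_catalog()] containing promoter intervals.
#' @return data.table with `gene_id`, `mean_meth` (percent, `NA` if missing)
#'   and `n_cpgs`.
#' @export
promoter_mean_methylation <- function(sample, catalog) {
  prom <- catalog[catalog$category == "promoter",
                  c("chrom", "start", "end", "gene_id"), with = FALSE]
  if (nrow(prom) == 0L) stopf("promoter_mean_methylation: catalog has no promoters")
  site <- data.table::data.table(chrom = sample$chrom, start = sample$pos,
                                 end = sample$pos + 1L,
                                 pct = 100 * sample$count_meth / sample$count_total)
  pk <- data.table::copy(prom)
  data.table::setkey(pk, chrom, start, end)
  data.table::setkey(site, chrom, start, end)
  ov <- data.table::foverlaps(site, pk, nomatch = NULL)
  agg <- ov[, .(mean_meth = mean(pct), n_cpgs = .N), by = gene_id]
  out <- data.table::data.table(gene_id = unique(prom$gene_id))
  out <- agg[out, on = "gene_id"]
  out[is.na(n_cpgs), n_cpgs := 0L]
  data.table::setcolorder(out, c("gene_id", "mean_meth", "n_cpgs"))
  out[]
}

#' Pairwise Pearson correlation matrix
#'
#' @param values numeric matrix with at least 3 rows (observations) and 2
#'   columns (samples). Zero-variance columns yield `NA` entries (undefined),
#'   never 0.
#' @return symmetric correlation matrix with unit diagonal for well-defined
#'   columns.
#' @export
pearson_matrix <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2L) stopf("pearson_matrix: need at least 2 columns")
  if (nrow(values) < 3L) stopf("pearson_matrix: need at least 3 rows")
  sds <- apply(values, 2, stats::sd)
  R <- suppressWarnings(stats::cor(values))
  R[sds == 0, ] <- NA_real_
  R[, sds == 0] <- NA_real_
  diag(R)[sds > 0] <- 1
  R
}

#' Promoter methylation vs expression strata
#'
#' Divides genes into methylation bins of their promoter mean and summarizes
#' expression (FPKM) per bin, with all pairwise two-tailed Welch t-tests.
#' Bins with fewer than 2 genes are flagged and their tests skipped.
#'
#' @param promoter_means data.table from [promoter_mean_methylation()] (or any
#'   table with `gene_id`, `mean_meth`).
#' @param fpkm named numeric vector of per-gene FPKM values (one sample or a
#'   mean over samples).
#' @param edges methylation bin edges in percent.
#' @return list with `summary` (bin, n, mean_fpkm, sem) and `tests`
#'   (bin1, bin2, t, p_value, skipped).
#' @export
methylation_expression_strata <- function(promoter_means, fpkm,
                                          edges = c(0, 25, 50, 75, 100)) {
  pm <- data.table::as.data.table(promoter_means)
  pm <- pm[!is.na(mean_meth) & gene_id %in% names(fpkm)]
  if (nrow(pm) == 0L) stopf("methylation_expression_strata: no genes matched")
  labs <- bin_labels(edges)
  pm[, bin := cut(mean_meth, breaks = edges, include.lowest = TRUE,
                  labels = labs)]
  pm[, fpkm := fpkm[gene_id]]
  summ <- pm[, .(n = .N, mean_fpkm = mean(fpkm),
                 sem = stats::sd(fpkm) / sqrt(.N)), by = bin]
  summ <- summ[data.table::data.table(bin = factor(labs, levels = labs)),
               on = "bin"]
  summ[is.na(n), n := 0L]

  pairs <- utils::combn(labs, 2)
  tests <- data.table::rbindlist(lapply(seq_len(ncol(pairs)), function(i) {
    a <- pm[bin == pairs[1, i], fpkm]
    b <- pm[bin == pairs[2, i], fpkm]
    if (length(a) < 2L || length(b) < 2L) {
      data.table::data.table(bin1 = pairs[1, i], bin2 = pairs[2, i],
                             t = NA_real_, p_value = NA_real_, skipped = TRUE)
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)  # Welch, two-tailed
      data.table::data.table(bin1 = pairs[1, i], bin2 = pairs[2, i],
                             t = unname(tt$statistic), p_value = tt$p.value,
                             skipped = FALSE)
    }
  }))
  list(summary = summ[], tests = tests)
}
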