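#' FPKM from a count matrix
#'
#' `FPKM = count / (gene_length_kb * library_size_millions)` where the
#' library size of a sample is its total assigned counts.
#'
#' @param counts genes x samples numeric matrix with gene rownames.
#' @param lengths named vector of gene lengths in bp (summed exons).
#' @return FPKM matrix with the same dimnames.
#' @export
compute_fpkm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stopf("compute_fpkm: counts need gene rownames")
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing))
    stopf("compute_fpkm: genes absent from lengths (e.g. %s)", missing[1])
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) stopf("compute_fpkm: gene lengths must be positive")
  lib <- colSums(counts)
  if (any(lib <= 0)) stopf("compute_fpkm: zero library size in sample %s",
                           colnames(counts)[which(lib <= 0)[1]])
  sweep(counts / (len / 1000), 2, lib / 1e6, "/")
}

# DESeq-style median-of-ratios size factors against a reference built from
# the given columns (genes with zero counts in any reference column are
# excluded from the reference)
size_factors_mor <- function(counts, ref_cols) {
  ref <- counts[, ref_cols, drop = FALSE]
  use <- rowSums(ref == 0) == 0
  if (sum(use) < 10)
    use <- rowSums(ref) > 0  # degenerate fallback for tiny matrices
  log_geo <- rowMeans(log(pmax(ref[use, , drop = FALSE], 0.5)))
  apply(counts[use, , drop = FALSE], 2, function(col) {
    stats::median(exp(log(pmax(col, 0.5)) - log_geo))
  })
}

# mean-dispersion trend alpha(mu) = a0 + a1 / mu fitted to per-gene
# method-of-moments dispersions of the normalized control counts; raw
# per-gene values are extremely noisy with few controls, so the fit goes
# through binned medians rather than the raw cloud
fit_dispersion_trend <- function(norm_controls) {
  mu <- rowMeans(norm_controls)
  v <- apply(norm_controls, 1, stats::var)
  raw <- (v - mu) / mu^2
  use <- is.finite(raw) & raw > 0 & mu > 1
  fallback <- stats::median(raw[is.finite(raw) & raw > 0], na.rm = TRUE)
  if (!is.finite(fallback)) fallback <- 0.1
  a0 <- max(fallback, 0.01)
  a1 <- 0
  if (sum(use) >= 20) {
    qs <- stats::quantile(mu[use], probs = seq(0, 1, length.out = 9))
    b <- cut(mu[use], breaks = unique(qs), include.lowest = TRUE)
    med <- tapply(raw[use], b, stats::median)
    mid <- tapply(mu[use], b, stats::median)
    ok <- is.finite(med) & is.finite(mid)
    if (sum(ok) >= 3) {
      fit <- stats::lm(med[ok] ~ I(1 / mid[ok]))
      a0 <- max(unname(stats::coef(fit)[1]), 1e-4)
      a1 <- max(unname(stats::coef(fit)[2]), 0)
    }
  }
  function(m) pmax(a0 + a1 / pmax(m, 1e-8), 1e-6)
}

#' Single-tumor differential expression against averaged controls
#'
#' A defined simplified test standing in for a full negative-binomial GLM,
#' suited to the one-tumor-versus-control-panel design: counts are normalized
#' with median-of-ratios size factors (controls as reference); each gene's
#' control mean and a genome-wide mean-dispersion trend (method of moments on
#' the controls, fitted as `a0 + a1/mu`) parameterize a negative binomial
#' null; the two-sided p-value is the doubled tail probability of a
#' normalized tumor count as or more extreme than observed. Fold changes are
#' ratios of FPKM means with a pseudo-FPKM added to both sides. A gene is
#' significant when the fold change passes `de_fc_threshold` (either
#' direction) and p is below `alpha`.
#'
#' @param counts genes x samples count matrix (gene rownames).
#' @param lengths named gene length vector (bp).
#' @param tumor_id column name of the tumor sample.
#' @param control_ids column names of at least two control samples.
#' @param config a [pipeline_config()].
#' @return data.table per gene: `gene_id`, `base_mean` (normalized control
#'   mean), `control_fpkm`, `tumor_fpkm`, `fold_change`, `log2fc`,
#'   `p_value`, `significant`.
#' @export
differential_expression <- function(counts, lengths, tumor_id, control_ids,
                                    config = pipeline_config()) {
  counts <- as.matrix(counts)
  if (length(control_ids) < 2L)
    stopf("differential_expression: need at least 2 controls")
  if (!tumor_id %in% colnames(counts))
    stopf("differential_expression: tumor %s not in counts", tumor_id)
  if (!all(control_ids %in% colnames(counts)))
    stopf("differential_expression: controls missing from counts")
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing))
    stopf("differential_expression: gene %s absent from lengths", missing[1])

  cols <- c(control_ids, tumor_id)
  sub <- counts[, cols, drop = FALSE]
  sf <- size_factors_mor(sub, ref_cols = control_ids)
  norm <- sweep(sub, 2, sf, "/")
  norm_ctrl <- norm[, control_ids, drop = FALSE]
  mu <- rowMeans(norm_ctrl)
  disp_fun <- fit_dispersion_trend(norm_ctrl)
  alpha_g <- disp_fun(mu)
  size_g <- 1 / alpha_g
  x <- round(norm[, tumor_id])

  p_lo <- stats::pnbinom(x, mu = pmax(mu, 1e-8), size = size_g)
  p_hi <- 1 - stats::pnbinom(x - 1, mu = pmax(mu, 1e-8), size = size_g)
  p <- pmin(1, 2 * pmin(p_lo, p_hi))
  p[mu <= 0 & x == 0] <- 1

  fpkm <- compute_fpkm(counts[, cols, drop = FALSE], lengths)
  ctrl_fpkm <- rowMeans(fpkm[, control_ids, drop = FALSE])
  tum_fpkm <- fpkm[, tumor_id]
  fc <- (tum_fpkm + config$pseudo_fpkm) / (ctrl_fpkm + config$pseudo_fpkm)

  data.table::data.table(
    gene_id = rownames(counts),
    base_mean = mu,
    control_fpkm = ctrl_fpkm,
    tumor_fpkm = tum_fpkm,
    fold_change = fc,
    log2fc = log2(fc),
    p_value = p,
    significant = (fc >= config$de_fc_threshold |
                     fc <= 1 / config$de_fc_threshold) & p < config$alpha)
}

#' Highly expressed gene set
#'
#' @param fpkm FPKM matrix (or named vector).
#' @param threshold FPKM cutoff, inclusive.
#' @param sample optional column to evaluate; default is the per-gene mean
#'   over all samples.
#' @return character vector of gene ids with FPKM at or above the threshold.
#' @export
high_expression_set <- function(fpkm, threshold = 5, sample = NULL) {
  v <- if (is.matrix(fpkm)) {
    if (is.null(sample)) rowMeans(fpkm) else fpkm[, sample]
  } else fpkm
  names(v)[v >= threshold]
}
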