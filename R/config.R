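#' Simulation configuration
#'
#' Describes a synthetic WGBS + RNA-seq experiment: a small genome with CpG
#' sites, gene models, enhancers and repeats; a panel of near-identical normal
#' control methylomes; tumor methylomes carrying planted hypo- and
#' hypermethylated regions (hypo-skewed by default); and an expression count
#' matrix in which a subset of genes is inversely coupled to promoter
#' methylation.
#'
#' Methylation latent fractions are drawn from a three-compartment mixture
#' (high / low / intermediate) so that the genome is mostly highly methylated,
#' as in normal T-cell methylomes, while promoters of a configurable fraction
#' of genes are lowly methylated. Controls share site-level latent fractions
#' and differ only by a small per-sample perturbation plus binomial sampling at
#' the sequenced depth.
#'
#' @param n_chromosomes number of chromosomes to simulate.
#' @param chrom_length length of each chromosome in bp.
#' @param cpg_spacing_mean mean distance between consecutive CpG sites (bp);
#'   gaps are `2 + Geometric`, so sites never collide.
#' @param n_controls number of normal control methylomes (default 5).
#' @param n_tumors number of tumor methylomes (default 7).
#' @param n_expression_controls number of control RNA-seq samples (default 4).
#' @param n_expression_tumors number of tumor RNA-seq samples (default 10).
#' @param depth_mean mean sequencing depth per CpG; depths are Poisson
#'   truncated at 1 so every simulated site is observed and the coverage
#'   filter acts non-trivially.
#' @param baseline_high_meth mean latent methylation of the high compartment.
#' @param baseline_low_meth mean latent methylation of the low compartment.
#' @param frac_low_meth_promoters fraction of genes whose promoter is lowly
#'   methylated (and therefore highly expressed under the inverse coupling).
#' @param frac_mid_meth_promoters fraction of genes with intermediate promoter
#'   methylation (target drawn uniformly in 0.28-0.72), so promoter-level
#'   methylation bins are all populated.
#' @param frac_low_cpgs,frac_mid_cpgs genome-wide fractions of CpGs in the low
#'   and intermediate latent compartments (the remainder is high).
#' @param latent_concentration Beta concentration of the high/low compartments;
#'   smaller values give more site-to-site variability.
#' @param control_noise_sd per-control perturbation of the latent fraction
#'   (controls are near-identical).
#' @param tumor_noise_sd per-tumor baseline perturbation outside planted
#'   regions (tumor heterogeneity; independent per tumor, not copied from
#'   controls).
#' @param n_planted_hypo,n_planted_hyper numbers of planted hypo- and
#'   hypermethylated regions (hypo-skewed by default). Promoter regions of
#'   coupled genes count toward these totals.
#' @param planted_effect methylation shift applied in carrier tumors, as a
#'   fraction in `[0.1, 0.8]`.
#' @param planted_width_cpgs number of consecutive CpGs per planted region
#'   (>= 3); regions are placed on runs with inter-CpG gaps < 100 bp so a
#'   correct caller can recover them.
#' @param recurrence_schedule optional list (one integer vector per planted
#'   region, in planting order) giving the carrier tumor indices. `NULL` uses
#'   a deterministic default: coupled promoter regions alternate between all
#'   tumors and all-but-one; background regions cycle through all / all-but-one
#'   / a small random subset.
#' @param n_genes number of genes.
#' @param coupled_gene_fraction fraction of genes whose expression is coupled
#'   to a planted promoter region.
#' @param coupled_hyper_fraction fraction of the coupled genes that receive a
#'   hypermethylated (expression-down) promoter region; the rest are
#'   hypomethylated/expression-up.
#' @param expression_dispersion negative-binomial dispersion of counts.
#' @param fold_change_coupled expression fold change applied to coupled genes
#'   in carrier tumors (default 10).
#' @param expression_coupling strength of the inverse promoter-methylation ->
#'   expression coupling: baseline mean FPKM is proportional to
#'   `2^(expression_coupling * (1 - promoter_methylation))`.
#' @param fpkm_scale FPKM of a fully methylated promoter's gene, before gene
#'   level noise.
#' @param gene_noise_sd lognormal sd of per-gene baseline expression.
#' @param library_size_mean mean RNA-seq library size (counts per sample).
#' @param seed integer seed; identical configurations (including the seed)
#'   reproduce outputs bit for bit.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chrom_length = 1.2e6,
                       cpg_spacing_mean = 60,
                       n_controls = 5L,
                       n_tumors = 7L,
                       n_expression_controls = 4L,
                       n_expression_tumors = 10L,
                       depth_mean = 30,
                       baseline_high_meth = 0.85,
                       baseline_low_meth = 0.08,
                       frac_low_meth_promoters = 0.12,
                       frac_mid_meth_promoters = 0.15,
                       frac_low_cpgs = 0.20,
                       frac_mid_cpgs = 0.10,
                       latent_concentration = 15,
                       control_noise_sd = 0.01,
                       tumor_noise_sd = 0.02,
                       n_planted_hypo = 16L,
                       n_planted_hyper = 8L,
                       planted_effect = 0.4,
                       planted_width_cpgs = 6L,
                       recurrence_schedule = NULL,
                       n_genes = 240L,
                       coupled_gene_fraction = 0.05,
                       coupled_hyper_fraction = 1 / 3,
                       expression_dispersion = 0.2,
                       fold_change_coupled = 10,
                       expression_coupling = 6,
                       fpkm_scale = 0.5,
                       gene_noise_sd = 0.5,
                       library_size_mean = 2e7,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.numeric(chrom_length),
    cpg_spacing_mean = as.numeric(cpg_spacing_mean),
    n_controls = as.integer(n_controls),
    n_tumors = as.integer(n_tumors),
    n_expression_controls = as.integer(n_expression_controls),
    n_expression_tumors = as.integer(n_expression_tumors),
    depth_mean = as.numeric(depth_mean),
    baseline_high_meth = baseline_high_meth,
    baseline_low_meth = baseline_low_meth,
    frac_low_meth_promoters = frac_low_meth_promoters,
    frac_mid_meth_promoters = frac_mid_meth_promoters,
    frac_low_cpgs = frac_low_cpgs,
    frac_mid_cpgs = frac_mid_cpgs,
    latent_concentration = latent_concentration,
    control_noise_sd = control_noise_sd,
    tumor_noise_sd = tumor_noise_sd,
    n_planted_hypo = as.integer(n_planted_hypo),
    n_planted_hyper = as.integer(n_planted_hyper),
    planted_effect = planted_effect,
    planted_width_cpgs = as.integer(planted_width_cpgs),
    recurrence_schedule = recurrence_schedule,
    n_genes = as.integer(n_genes),
    coupled_gene_fraction = coupled_gene_fraction,
    coupled_hyper_fraction = coupled_hyper_fraction,
    expression_dispersion = expression_dispersion,
    fold_change_coupled = fold_change_coupled,
    expression_coupling = expression_coupling,
    fpkm_scale = fpkm_scale,
    gene_noise_sd = gene_noise_sd,
    library_size_mean = library_size_mean,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!is_count1(n_chromosomes, TRUE)) stopf("n_chromosomes must be a positive count")
    if (!is_number1(chrom_length, TRUE)) stopf("chrom_length must be positive")
    if (!is_number1(cpg_spacing_mean) || cpg_spacing_mean < 3)
      stopf("cpg_spacing_mean must be >= 3 bp")
    for (nm in c("n_controls", "n_tumors", "n_expression_controls",
                 "n_expression_tumors", "n_genes")) {
      if (!is_count1(cfg[[nm]], TRUE)) stopf("%s must be a positive count", nm)
    }
    if (!is_number1(depth_mean, TRUE)) stopf("depth_mean must be > 0")
    for (nm in c("baseline_high_meth", "baseline_low_meth",
                 "frac_low_meth_promoters", "frac_mid_meth_promoters",
                 "frac_low_cpgs", "frac_mid_cpgs",
                 "coupled_gene_fraction", "coupled_hyper_fraction")) {
      if (!is_fraction1(cfg[[nm]])) stopf("%s must be a fraction in [0, 1]", nm)
    }
    if (frac_low_cpgs + frac_mid_cpgs > 1)
      stopf("frac_low_cpgs + frac_mid_cpgs must not exceed 1")
    if (!is_number1(planted_effect) || planted_effect < 0.1 || planted_effect > 0.8)
      stopf("planted_effect must lie in [0.1, 0.8]")
    if (!is_count1(planted_width_cpgs) || planted_width_cpgs < 3)
      stopf("planted_width_cpgs must be a count >= 3")
    if (!is_count1(n_planted_hypo) || !is_count1(n_planted_hyper))
      stopf("planted region counts must be non-negative counts")
    if (!is.null(recurrence_schedule)) {
      if (!is.list(recurrence_schedule) ||
          length(recurrence_schedule) != n_planted_hypo + n_planted_hyper)
        stopf("recurrence_schedule must be a list with one entry per planted region (%d)",
              n_planted_hypo + n_planted_hyper)
      ok <- vapply(recurrence_schedule, function(v) {
        length(v) >= 1 && all(v == floor(v)) && all(v >= 1) && all(v <= n_tumors) &&
          !anyDuplicated(v)
      }, logical(1))
      if (!all(ok))
        stopf("recurrence_schedule entries must be non-empty subsets of tumor indices 1..%d",
              n_tumors)
    }
    for (nm in c("expression_dispersion", "fold_change_coupled", "fpkm_scale",
                 "library_size_mean", "latent_concentration")) {
      if (!is_number1(cfg[[nm]], TRUE)) stopf("%s must be positive", nm)
    }
    for (nm in c("control_noise_sd", "tumor_noise_sd", "gene_noise_sd",
                 "expression_coupling")) {
      if (!is_number1(cfg[[nm]]) || cfg[[nm]] < 0) stopf("%s must be >= 0", nm)
    }
    if (!is_count1(seed)) stopf("seed must be a non-negative integer")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d chromosome(s) x %s bp, CpG spacing ~%g bp\n",
              x$n_chromosomes, format(x$chrom_length, big.mark = ","),
              x$cpg_spacing_mean))
  cat(sprintf("  samples: %d controls + %d tumors (WGBS), %d + %d (RNA-seq)\n",
              x$n_controls, x$n_tumors,
              x$n_expression_controls, x$n_expression_tumors))
  cat(sprintf("  planted: %d hypo + %d hyper regions, effect %.2f, width %d CpGs\n",
              x$n_planted_hypo, x$n_planted_hyper, x$planted_effect,
              x$planted_width_cpgs))
  cat(sprintf("  genes: %d (%.0f%% coupled, fold change %g)\n",
              x$n_genes, 100 * x$coupled_gene_fraction, x$fold_change_coupled))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Analysis pipeline configuration
#'
#' Holds every threshold used by the analysis stages. Defaults are the values
#' the pipeline was designed around: a 5x minimum coverage filter, four
#' methylation bins, a promoter window of 1,500 bp upstream to 500 bp
#' downstream of the TSS, a 10 percentage-point DMC threshold, DMRs of at
#' least 3 consecutive same-direction DMCs separated by at most 100 bp, a
#' Mann-Whitney region test at alpha = 0.05, differential expression at fold
#' change >= 1.5 with p < 0.05, a 2-fold core expression signature, and
#' promoter-integration requiring a promoter DMR in at least 6 of 7 tumors.
#'
#' @param min_depth minimum per-CpG sequencing depth (reads, inclusive).
#' @param bin_edges methylation bin edges in percent; the first bin is closed
#'   `[e1, e2]`, later bins are half-open `(ei, ei+1]`.
#' @param promoter_upstream,promoter_downstream promoter window around the TSS
#'   in bp (strand-oriented).
#' @param dmc_min_delta minimum absolute methylation change in percentage
#'   points for a differentially methylated cytosine (inclusive).
#' @param dmr_min_cpgs minimum number of consecutive DMCs per region.
#' @param dmr_max_gap maximum distance in bp between consecutive DMCs within a
#'   region (inclusive).
#' @param alpha significance level for the region test and expression test.
#' @param de_fc_threshold fold-change threshold for per-tumor differential
#'   expression.
#' @param core_expr_fc fold-change threshold for the core expression signature.
#' @param recurrence_all if `TRUE` the core methylation signature requires
#'   support in every tumor (`n_required = n_tumors`).
#' @param integration_min_tumors minimum number of tumors with a same-direction
#'   promoter DMR for a gene to enter the integrated lists.
#' @param integration_expr_fc fold-change threshold on the expression side of
#'   the integration.
#' @param integration_expr_min_tumors minimum number of tumors whose expression
#'   must change for an integrated gene; `NULL` means a majority plus one
#'   (`ceiling(n/2) + 1`).
#' @param high_expression_fpkm FPKM threshold (inclusive) defining highly
#'   expressed genes.
#' @param fdr apply Benjamini-Hochberg correction across candidate regions
#'   before the alpha cut (off by default; the region test is reported raw).
#' @param pseudo_fpkm pseudo-FPKM added to numerator and denominator of fold
#'   changes to stabilize zeros.
#'
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_depth = 5L,
                            bin_edges = c(0, 25, 50, 75, 100),
                            promoter_upstream = 1500L,
                            promoter_downstream = 500L,
                            dmc_min_delta = 10,
                            dmr_min_cpgs = 3L,
                            dmr_max_gap = 100L,
                            alpha = 0.05,
                            de_fc_threshold = 1.5,
                            core_expr_fc = 2,
                            recurrence_all = TRUE,
                            integration_min_tumors = 6L,
                            integration_expr_fc = 2,
                            integration_expr_min_tumors = NULL,
                            high_expression_fpkm = 5,
                            fdr = FALSE,
                            pseudo_fpkm = 0.1) {
  cfg <- list(
    min_depth = as.integer(min_depth),
    bin_edges = as.numeric(bin_edges),
    promoter_upstream = as.integer(promoter_upstream),
    promoter_downstream = as.integer(promoter_downstream),
    dmc_min_delta = as.numeric(dmc_min_delta),
    dmr_min_cpgs = as.integer(dmr_min_cpgs),
    dmr_max_gap = as.numeric(dmr_max_gap),
    alpha = as.numeric(alpha),
    de_fc_threshold = as.numeric(de_fc_threshold),
    core_expr_fc = as.numeric(core_expr_fc),
    recurrence_all = isTRUE(recurrence_all),
    integration_min_tumors = as.integer(integration_min_tumors),
    integration_expr_fc = as.numeric(integration_expr_fc),
    integration_expr_min_tumors =
      if (is.null(integration_expr_min_tumors)) NULL
      else as.integer(integration_expr_min_tumors),
    high_expression_fpkm = as.numeric(high_expression_fpkm),
    fdr = isTRUE(fdr),
    pseudo_fpkm = as.numeric(pseudo_fpkm)
  )
  if (!is_count1(cfg$min_depth)) stopf("min_depth must be a non-negative count")
  if (length(cfg$bin_edges) < 2 || is.unsorted(cfg$bin_edges, strictly = TRUE))
    stopf("bin_edges must be strictly increasing with at least two values")
  if (cfg$dmc_min_delta < 0) stopf("dmc_min_delta must be >= 0")
  if (cfg$dmr_min_cpgs < 1) stopf("dmr_min_cpgs must be >= 1")
  if (cfg$dmr_max_gap < 0) stopf("dmr_max_gap must be >= 0")
  if (cfg$alpha < 0 || cfg$alpha > 1) stopf("alpha must lie in [0, 1]")
  if (cfg$de_fc_threshold < 1) stopf("de_fc_threshold must be >= 1")
  if (cfg$core_expr_fc < 1) stopf("core_expr_fc must be >= 1")
  if (cfg$integration_expr_fc < 1) stopf("integration_expr_fc must be >= 1")
  if (cfg$pseudo_fpkm < 0) stopf("pseudo_fpkm must be >= 0")
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  coverage >= %dx; DMC |delta| >= %g pp; DMR >= %d CpGs, gap <= %g bp; alpha %g%s\n",
              x$min_depth, x$dmc_min_delta, x$dmr_min_cpgs, x$dmr_max_gap,
              x$alpha, if (x$fdr) " (BH)" else ""))
  cat(sprintf("  promoter: -%d..+%d bp around TSS; DE FC >= %g; core FC >= %g\n",
              x$promoter_upstream, x$promoter_downstream,
              x$de_fc_threshold, x$core_expr_fc))
  invisible(x)
}

# expression-side tumor quorum for the integration step
integration_expr_quorum <- function(config, n_expression_tumors) {
  config$integration_expr_min_tumors %||%
    as.integer(ceiling(n_expression_tumors / 2) + 1)
}
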