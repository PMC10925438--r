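#' Run the full pipeline on simulated data
#'
#' Orchestrates every stage: simulation (genome, truth, methylomes,
#' expression), descriptive profiling, per-tumor DMR calling, genomic
#' annotation, per-tumor differential expression, the cross-tumor core
#' signatures and the promoter-methylation x expression integration. All
#' stage outputs are written under `out_dir` as plain-text tables and a run
#' manifest (configuration snapshot, seed, per-file MD5 digests, per-stage
#' tallies, timestamps) is written as `manifest.json`. A second run with the
#' same configuration reproduces every output file bit for bit.
#'
#' @param config a [sim_config()]; `seed` (if given) overrides its seed.
#' @param pipe a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param seed optional integer overriding `config$seed`.
#' @param quiet suppress per-stage messages.
#' @return (invisibly) a list with all in-memory stage results plus the
#'   `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), pipe = pipeline_config(),
                         out_dir = tempfile("dmrpipe_run_"), seed = NULL,
                         quiet = FALSE) {
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    validate_sim_config(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  files <- character()
  note <- function(path) { files[length(files) + 1] <<- path; path }
  stats <- list()

  # ---- stage: simulate -----------------------------------------------------
  sim <- simulate_all(config)
  sim_dir <- file.path(out_dir, "sim")
  dir.create(sim_dir, showWarnings = FALSE)
  for (nm in names(sim$methylomes))
    write_bismark_coverage(sim$methylomes[[nm]],
                           note(file.path(sim_dir, paste0(nm, ".cov.tsv"))))
  for (cat_i in unique(sim$genome$catalog$category))
    write_bed(sim$genome$catalog[category == cat_i],
              note(file.path(sim_dir, paste0(cat_i, ".bed"))))
  write_counts(sim$expression$counts, note(file.path(sim_dir, "counts.tsv")))
  write_gene_lengths(sim$expression$lengths,
                     note(file.path(sim_dir, "gene_lengths.tsv")))
  write_truth(sim$truth, file.path(sim_dir, "truth"))
  note(file.path(sim_dir, "truth.regions.tsv"))
  note(file.path(sim_dir, "truth.genes.tsv"))
  stats$simulate <- list(n_cpgs = nrow(sim$genome$cpgs),
                         n_genes = nrow(sim$genome$genes),
                         n_planted = nrow(sim$truth$planted_dmrs),
                         n_coupled = nrow(sim$truth$coupled_genes))
  say("simulate: %d CpGs, %d genes, %d planted regions, %d coupled genes",
      stats$simulate$n_cpgs, stats$simulate$n_genes,
      stats$simulate$n_planted, stats$simulate$n_coupled)

  controls <- sim$methylomes[grep("^ctrl_", names(sim$methylomes))]
  tumors <- sim$methylomes[grep("^tumor_", names(sim$methylomes))]

  # ---- stage: profile ------------------------------------------------------
  prof_dir <- file.path(out_dir, "profile")
  dir.create(prof_dir, showWarnings = FALSE)
  filtered_controls <- lapply(controls, filter_by_coverage, pipe$min_depth)
  common <- intersect_common_cpgs(filtered_controls)
  ctrl_R <- pearson_matrix(common$fractions)
  utils::write.table(round(ctrl_R, 6),
                     note(file.path(prof_dir, "control_pearson.tsv")),
                     sep = "\t", quote = FALSE)
  cpg_bins <- bin_values(100 * common$fractions[, 1], pipe$bin_edges)
  prom_means <- promoter_mean_methylation(filtered_controls[[1]],
                                          sim$genome$catalog)
  data.table::fwrite(prom_means,
                     note(file.path(prof_dir, "promoter_methylation.tsv")),
                     sep = "\t")
  fpkm <- compute_fpkm(sim$expression$counts, sim$expression$lengths)
  ctrl_cols <- grep("^ectrl_", colnames(fpkm), value = TRUE)
  strata <- methylation_expression_strata(
    prom_means, rowMeans(fpkm[, ctrl_cols, drop = FALSE]), pipe$bin_edges)
  data.table::fwrite(strata$summary,
                     note(file.path(prof_dir, "strata_summary.tsv")), sep = "\t")
  data.table::fwrite(strata$tests,
                     note(file.path(prof_dir, "strata_tests.tsv")), sep = "\t")
  stats$profile <- list(n_common_cpgs = nrow(common$positions),
                        min_control_R = min(ctrl_R),
                        cpg_bins = as.list(cpg_bins))
  say("profile: %d CpGs covered >= %dx in all controls, min control R = %.3f",
      stats$profile$n_common_cpgs, pipe$min_depth, stats$profile$min_control_R)

  # ---- stage: dmr ----------------------------------------------------------
  dmr_dir <- file.path(out_dir, "dmr")
  dir.create(dmr_dir, showWarnings = FALSE)
  profile <- average_controls(controls, pipe)
  dmr_list <- lapply(tumors, function(tm) call_dmrs_profiled(tm, profile, pipe))
  for (nm in names(dmr_list))
    write_dmrs(dmr_list[[nm]], note(file.path(dmr_dir, paste0(nm, ".dmrs.tsv"))))
  stats$dmr <- lapply(dmr_list, function(d) as.list(dmr_direction_counts(d)))
  say("dmr: %s DMRs per tumor",
      paste(vapply(dmr_list, nrow, integer(1)), collapse = "/"))

  # ---- stage: annotate -----------------------------------------------------
  ann_dir <- file.path(out_dir, "annotate")
  dir.create(ann_dir, showWarnings = FALSE)
  index <- build_interval_index(sim$genome$catalog)
  annotated <- lapply(dmr_list, annotate_dmrs, index = index)
  cat_counts <- data.table::rbindlist(
    lapply(annotated, function(a) a$category_counts), idcol = "tumor")
  data.table::fwrite(cat_counts,
                     note(file.path(ann_dir, "category_counts.tsv")), sep = "\t")
  stats$annotate <- list(total_hits = sum(cat_counts$n))

  # ---- stage: differential expression --------------------------------------
  de_dir <- file.path(out_dir, "de")
  dir.create(de_dir, showWarnings = FALSE)
  ectrl <- grep("^ectrl_", colnames(sim$expression$counts), value = TRUE)
  etum <- grep("^etumor_", colnames(sim$expression$counts), value = TRUE)
  de_list <- lapply(stats::setNames(etum, etum), function(tm) {
    differential_expression(sim$expression$counts, sim$expression$lengths,
                            tm, ectrl, pipe)
  })
  for (nm in names(de_list))
    data.table::fwrite(de_list[[nm]],
                       note(file.path(de_dir, paste0(nm, ".de.tsv"))), sep = "\t")
  stats$de <- lapply(de_list, function(d) sum(d$significant))
  say("de: %s significant genes per tumor",
      paste(unlist(stats$de), collapse = "/"))

  # ---- stage: signatures ---------------------------------------------------
  sig_dir <- file.path(out_dir, "signature")
  dir.create(sig_dir, showWarnings = FALSE)
  n_req <- if (pipe$recurrence_all) length(dmr_list) else
    min(pipe$integration_min_tumors, length(dmr_list))
  core_meth <- recurrent_dmrs(dmr_list, n_required = n_req)
  data.table::fwrite(core_meth$regions,
                     note(file.path(sig_dir, "core_methylation.tsv")), sep = "\t")
  fc_mat <- do.call(cbind, lapply(de_list, function(d) d$fold_change))
  rownames(fc_mat) <- de_list[[1]]$gene_id
  core_expr <- core_expression_signature(fc_mat, pipe$core_expr_fc)
  writeLines(core_expr$up, note(file.path(sig_dir, "core_expression_up.txt")))
  writeLines(core_expr$down, note(file.path(sig_dir, "core_expression_down.txt")))
  dist <- signature_element_distribution(core_meth$regions, index)
  data.table::fwrite(dist$exclusive,
                     note(file.path(sig_dir, "core_meth_elements.tsv")), sep = "\t")
  stats$signature <- list(
    core_hypo = sum(core_meth$regions$direction == "hypo"),
    core_hyper = sum(core_meth$regions$direction == "hyper"),
    core_expr_up = length(core_expr$up),
    core_expr_down = length(core_expr$down))
  say("signature: %d hypo / %d hyper core regions; %d up / %d down core genes",
      stats$signature$core_hypo, stats$signature$core_hyper,
      stats$signature$core_expr_up, stats$signature$core_expr_down)

  # ---- stage: integrate ----------------------------------------------------
  freq <- promoter_dmr_frequency(annotated, sim$genome$catalog)
  data.table::fwrite(freq,
                     note(file.path(sig_dir, "promoter_dmr_frequency.tsv")),
                     sep = "\t")
  integrated <- integrate_signatures(freq, de_list, pipe)
  data.table::fwrite(integrated$hypo_up,
                     note(file.path(sig_dir, "integrated_hypo_up.tsv")), sep = "\t")
  data.table::fwrite(integrated$hyper_down,
                     note(file.path(sig_dir, "integrated_hyper_down.tsv")),
                     sep = "\t")
  stats$integrate <- list(hypo_up = nrow(integrated$hypo_up),
                          hyper_down = nrow(integrated$hyper_down))
  say("integrate: %d hypo-up and %d hyper-down genes",
      stats$integrate$hypo_up, stats$integrate$hyper_down)

  # ---- manifest ------------------------------------------------------------
  digests <- tools::md5sum(files)
  names(digests) <- sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                                         out_dir), "/?"), "", names(digests))
  manifest <- list(
    package_version = as.character(utils::packageVersion("dmrpipe")),
    seed = config$seed,
    sim_config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    pipeline_config = unclass(pipe)[!vapply(unclass(pipe), is.null, logical(1))],
    stage_stats = stats,
    files = as.list(digests),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(sim = sim, profile = list(common = common, pearson = ctrl_R,
                                           promoter_means = prom_means,
                                           strata = strata),
                 dmrs = dmr_list, annotated = annotated, de = de_list,
                 core_methylation = core_meth, core_expression = core_expr,
                 integrated = integrated, freq = freq, manifest = manifest,
                 out_dir = out_dir))
}
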