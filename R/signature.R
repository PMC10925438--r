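#' Cross-tumor recurrent DMRs (core methylation signature)
#'
#' Because different tumors' DMRs never share exact boundaries, recurrence is
#' defined at base-pair resolution: a core region is a maximal genomic
#' interval in which at least `n_required` tumors have a same-direction DMR
#' covering every base. Hypo- and hypermethylated signatures are computed
#' independently; each core region reports its supporting DMRs.
#'
#' @param dmr_list named list of per-tumor DMR tables (same coordinate
#'   convention).
#' @param n_required minimum number of supporting tumors; must not exceed the
#'   number of tumors.
#' @return an object of class `core_methylation_signature`: list with
#'   `regions` (chrom, start, end, direction), `support` (region, tumor,
#'   and the supporting DMR's coordinates) and `n_required`.
#' @export
recurrent_dmrs <- function(dmr_list, n_required = length(dmr_list)) {
  n_tumors <- length(dmr_list)
  if (n_required > n_tumors)
    stopf("recurrent_dmrs: n_required (%d) exceeds the number of tumors (%d)",
          n_required, n_tumors)
  if (n_required < 1L) stopf("recurrent_dmrs: n_required must be >= 1")
  if (is.null(names(dmr_list)))
    names(dmr_list) <- sprintf("tumor_%d", seq_len(n_tumors))

  one_direction <- function(dir) {
    per <- lapply(names(dmr_list), function(tum) {
      d <- data.table::as.data.table(dmr_list[[tum]])
      d <- d[direction == dir]
      if (nrow(d) == 0L) return(NULL)
      data.table::data.table(chrom = d$chrom, start = d$start, end = d$end,
                             tumor = tum)
    })
    all_d <- data.table::rbindlist(per)
    if (is.null(all_d) || nrow(all_d) == 0L)
      return(list(regions = data.table::data.table(
        chrom = character(), start = numeric(), end = numeric(),
        direction = character()),
        support = data.table::data.table(region = integer(), tumor = character(),
                                         chrom = character(), start = numeric(),
                                         end = numeric())))
    # per-tumor DMRs are disjoint, so interval coverage depth equals the
    # number of distinct supporting tumors at each base
    gr <- GenomicRanges::GRanges(all_d$chrom,
                                 IRanges::IRanges(all_d$start + 1, all_d$end))
    cov <- GenomicRanges::coverage(gr)
    core <- IRanges::slice(cov, lower = n_required, rangesOnly = TRUE)
    regions <- data.table::rbindlist(lapply(names(core), function(ch) {
      r <- core[[ch]]
      if (length(r) == 0L) return(NULL)
      data.table::data.table(chrom = ch, start = IRanges::start(r) - 1,
                             end = IRanges::end(r), direction = dir)
    }))
    if (is.null(regions) || nrow(regions) == 0L)
      return(list(regions = data.table::data.table(
        chrom = character(), start = numeric(), end = numeric(),
        direction = character()),
        support = data.table::data.table(region = integer(), tumor = character(),
                                         chrom = character(), start = numeric(),
                                         end = numeric())))
    data.table::setorder(regions, chrom, start)
    rgr <- GenomicRanges::GRanges(regions$chrom,
                                  IRanges::IRanges(regions$start + 1, regions$end))
    hits <- GenomicRanges::findOverlaps(rgr, gr)
    support <- data.table::data.table(
      region = S4Vectors::queryHits(hits),
      tumor = all_d$tumor[S4Vectors::subjectHits(hits)],
      chrom = all_d$chrom[S4Vectors::subjectHits(hits)],
      start = all_d$start[S4Vectors::subjectHits(hits)],
      end = all_d$end[S4Vectors::subjectHits(hits)])
    list(regions = regions, support = support)
  }

  hypo <- one_direction("hypo")
  hyper <- one_direction("hyper")
  regions <- data.table::rbindlist(list(hypo$regions, hyper$regions))
  n_hypo <- nrow(hypo$regions)
  hyper$support[, region := region + n_hypo]
  support <- data.table::rbindlist(list(hypo$support, hyper$support))
  structure(list(regions = regions[], support = support[],
                 n_required = n_required, n_tumors = n_tumors),
            class = "core_methylation_signature")
}

#' @export
print.core_methylation_signature <- function(x, ...) {
  cat(sprintf("<core_methylation_signature> %d hypo + %d hyper regions (>= %d of %d tumors)\n",
              sum(x$regions$direction == "hypo"),
              sum(x$regions$direction == "hyper"),
              x$n_required, x$n_tumors))
  invisible(x)
}

#' Core gene expression signature
#'
#' Genes whose expression changes in the same direction in at least
#' `n_required` tumors: the up set requires a fold change of at least
#' `fc_threshold` in each, the down set a fold change of at most
#' `1 / fc_threshold`. The sets are disjoint by construction whenever
#' `n_required` exceeds half the tumors.
#'
#' @param fold_changes genes x tumors matrix of fold changes (tumor vs
#'   control mean), gene rownames.
#' @param fc_threshold fold-change threshold (>= 1).
#' @param n_required number of tumors required (default: all).
#' @return list with character vectors `up` and `down`.
#' @export
core_expression_signature <- function(fold_changes, fc_threshold = 2,
                                      n_required = ncol(fold_changes)) {
  fold_changes <- as.matrix(fold_changes)
  if (n_required > ncol(fold_changes))
    stopf("core_expression_signature: n_required exceeds the number of tumors")
  up <- rownames(fold_changes)[rowSums(fold_changes >= fc_threshold) >= n_required]
  down <- rownames(fold_changes)[rowSums(fold_changes <= 1 / fc_threshold) >= n_required]
  list(up = up, down = down)
}

#' Per-gene promoter DMR frequency across tumors
#'
#' For every gene, counts in how many tumors at least one hypo- (resp.
#' hypermethylated) DMR overlaps its promoter. A tumor contributes at most 1
#' per direction regardless of how many of its DMRs hit the promoter; the two
#' directions are tallied independently.
#'
#' @param annotated_list named list of `annotated_dmrs` (one per tumor, from
#'   [annotate_dmrs()]).
#' @param catalog a [feature_catalog()]; its promoter genes define the gene
#'   universe (genes without any promoter DMR get zero counts).
#' @return data.table `gene_id`, `hypo_count`, `hyper_count`.
#' @export
promoter_dmr_frequency <- function(annotated_list, catalog) {
  genes <- unique(catalog$gene_id[catalog$category == "promoter"])
  if (is.null(names(annotated_list)))
    names(annotated_list) <- sprintf("tumor_%d", seq_along(annotated_list))
  per <- data.table::rbindlist(lapply(names(annotated_list), function(tum) {
    a <- annotated_list[[tum]]
    h <- a$hits[category == "promoter" & !is.na(gene_id)]
    if (nrow(h) == 0L) return(NULL)
    h <- data.table::data.table(gene_id = h$gene_id,
                                direction = a$dmrs$direction[h$dmr])
    unique(h)[, tumor := tum]
  }))
  out <- data.table::data.table(gene_id = genes, hypo_count = 0L,
                                hyper_count = 0L)
  if (!is.null(per) && nrow(per)) {
    tall <- per[, .(n = data.table::uniqueN(tumor)), by = .(gene_id, direction)]
    hypo <- tall[direction == "hypo"]
    hyper <- tall[direction == "hyper"]
    out[hypo, on = "gene_id", hypo_count := i.n]
    out[hyper, on = "gene_id", hyper_count := i.n]
  }
  out[]
}

#' Integrate promoter methylation frequency with expression changes
#'
#' The hypo-up list contains genes with a hypomethylated promoter DMR in at
#' least `integration_min_tumors` tumors whose expression is increased (fold
#' change at least `integration_expr_fc` with p below alpha) in at least the
#' expression quorum of tumors; the hyper-down list is the mirror image
#' (hypermethylated promoters, expression decreased).
#'
#' @param freq promoter DMR frequencies from [promoter_dmr_frequency()].
#' @param de_list named list of per-tumor differential expression tables from
#'   [differential_expression()].
#' @param config a [pipeline_config()]; `integration_min_tumors`,
#'   `integration_expr_fc`, `integration_expr_min_tumors` (NULL = majority
#'   plus one) and `alpha` apply.
#' @return list with data.tables `hypo_up` and `hyper_down`: `gene_id`,
#'   promoter DMR tumor count, number of expression-changed tumors, mean fold
#'   change over the expression tumors.
#' @export
integrate_signatures <- function(freq, de_list, config = pipeline_config()) {
  n_expr <- length(de_list)
  quorum <- integration_expr_quorum(config, n_expr)
  fc_thr <- config$integration_expr_fc

  expr <- data.table::rbindlist(lapply(de_list, function(d) {
    data.table::data.table(gene_id = d$gene_id, fold_change = d$fold_change,
                           p_value = d$p_value)
  }), idcol = "tumor")
  stats_dt <- expr[, .(
    n_up = sum(fold_change >= fc_thr & p_value < config$alpha),
    n_down = sum(fold_change <= 1 / fc_thr & p_value < config$alpha),
    mean_fc = mean(fold_change)), by = gene_id]

  joined <- stats_dt[data.table::as.data.table(freq), on = "gene_id"]
  joined[is.na(n_up), `:=`(n_up = 0L, n_down = 0L, mean_fc = NA_real_)]

  hypo_up <- joined[hypo_count >= config$integration_min_tumors &
                      n_up >= quorum,
                    .(gene_id, hypo_count, n_tumors_up = n_up, mean_fc)]
  hyper_down <- joined[hyper_count >= config$integration_min_tumors &
                         n_down >= quorum,
                       .(gene_id, hyper_count, n_tumors_down = n_down, mean_fc)]
  data.table::setorder(hypo_up, gene_id)
  data.table::setorder(hyper_down, gene_id)
  list(hypo_up = hypo_up[], hyper_down = hyper_down[])
}
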