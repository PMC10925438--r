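#' Average control methylomes into a control profile
#'
#' Applies the coverage filter to every control, restricts to CpG sites
#' covered in all of them (strict intersection), and stores both the per-site
#' unweighted mean methylation fraction and the per-control aligned fractions
#' (the latter feed the region-level rank test).
#'
#' @param controls list of one or more [methylome_sample()]s.
#' @param config a [pipeline_config()].
#' @return an object of class `control_profile`: list with `sites`
#'   (data.table `chrom`, `pos`, `mean_fraction`, `n_controls_covered`),
#'   `fractions` (sites x controls matrix) and `n_controls`.
#' @export
average_controls <- function(controls, config = pipeline_config()) {
  if (length(controls) < 1L) stopf("average_controls: need at least one control")
  filtered <- lapply(controls, filter_by_coverage, min_depth = config$min_depth)
  if (length(filtered) == 1L) {
    s <- filtered[[1]]
    if (nrow(s) == 0L) stopf("average_controls: no sites pass the coverage filter")
    frac <- matrix(s$count_meth / s$count_total, ncol = 1,
                   dimnames = list(NULL, attr(s, "sample_id")))
    sites <- data.table::data.table(chrom = s$chrom, pos = s$pos,
                                    mean_fraction = frac[, 1],
                                    n_controls_covered = 1L)
  } else {
    common <- intersect_common_cpgs(filtered)
    if (nrow(common$positions) == 0L)
      stopf("average_controls: no CpG site is covered >= %dx in all %d controls",
            config$min_depth, length(controls))
    frac <- common$fractions
    sites <- data.table::data.table(
      chrom = common$positions$chrom, pos = common$positions$pos,
      mean_fraction = rowMeans(frac),
      n_controls_covered = length(controls))
  }
  structure(list(sites = sites, fractions = frac,
                 n_controls = length(controls)),
            class = "control_profile")
}

#' @export
print.control_profile <- function(x, ...) {
  cat(sprintf("<control_profile> %d sites covered in all %d control(s)\n",
              nrow(x$sites), x$n_controls))
  invisible(x)
}

#' Call differentially methylated cytosines (DMCs)
#'
#' Aligns a coverage-filtered tumor methylome with the control profile
#' (intersection of positions) and computes the methylation change in
#' percentage points (tumor minus control mean). Sites with an absolute
#' change of at least `dmc_min_delta` (inclusive) are DMCs; the direction is
#' the sign of the change.
#'
#' @param tumor a [methylome_sample()].
#' @param profile a `control_profile` from [average_controls()].
#' @param config a [pipeline_config()].
#' @return data.table of DMCs, position-sorted: `chrom`, `pos`, `delta`
#'   (percentage points), `direction` ("hypo"/"hyper"), `tumor_fraction`,
#'   `profile_row` (index into the profile, used by the region test).
#' @export
call_dmcs <- function(tumor, profile, config = pipeline_config()) {
  t_f <- filter_by_coverage(tumor, config$min_depth)
  sites <- data.table::copy(profile$sites)[, profile_row := .I]
  tt <- data.table::data.table(chrom = t_f$chrom, pos = t_f$pos,
                               tumor_fraction = t_f$count_meth / t_f$count_total)
  m <- sites[tt, on = c("chrom", "pos"), nomatch = NULL]
  m[, delta := 100 * (tumor_fraction - mean_fraction)]
  dmcs <- m[abs(delta) >= config$dmc_min_delta]
  dmcs[, direction := data.table::fifelse(delta < 0, "hypo", "hyper")]
  data.table::setorder(dmcs, chrom, pos)
  dmcs[, .(chrom, pos, delta, direction, tumor_fraction, profile_row)]
}

#' Segment DMCs into candidate regions
#'
#' Builds maximal runs of same-direction DMCs in which consecutive sites are
#' at most `dmr_max_gap` bp apart; a direction flip, a larger gap or a
#' chromosome change terminates a run. Runs of at least `dmr_min_cpgs`
#' members become candidate regions spanning the first to the last member CpG
#' (half-open, end = last position + 1) with `mean_delta` the mean of the
#' member deltas.
#'
#' @param dmcs position-sorted DMC table from [call_dmcs()].
#' @param config a [pipeline_config()].
#' @return data.table of candidates: `chrom`, `start`, `end`, `direction`,
#'   `n_cpgs`, `mean_delta`, plus a list column `members` holding the row
#'   indices of the member DMCs (into `dmcs`).
#' @export
segment_dmrs <- function(dmcs, config = pipeline_config()) {
  empty <- data.table::data.table(
    chrom = character(), start = numeric(), end = numeric(),
    direction = character(), n_cpgs = integer(), mean_delta = numeric(),
    members = list())
  if (nrow(dmcs) == 0L) return(empty)
  d <- data.table::as.data.table(dmcs)
  new_run <- c(TRUE,
               d$chrom[-1] != d$chrom[-nrow(d)] |
                 d$direction[-1] != d$direction[-nrow(d)] |
                 (d$pos[-1] - d$pos[-nrow(d)]) > config$dmr_max_gap)
  d[, run := cumsum(new_run)]
  d[, row := .I]
  cand <- d[, .(chrom = chrom[1], start = pos[1], end = pos[.N] + 1,
                direction = direction[1], n_cpgs = .N,
                mean_delta = mean(delta), members = list(row)),
            by = run][n_cpgs >= config$dmr_min_cpgs]
  if (nrow(cand) == 0L) return(empty)
  cand[, run := NULL]
  cand[]
}

#' Region-level Mann-Whitney U test
#'
#' Two-sided rank test of the tumor's per-CpG methylation fractions over a
#' region (one value per member CpG) against the pooled controls' per-CpG
#' fractions over the same region (one value per control per CpG). Exact for
#' small tie-free groups, tie-corrected normal approximation otherwise (see
#' [mwu_test()]).
#'
#' @param tumor_fractions numeric vector of the tumor's fractions at the
#'   member CpGs.
#' @param control_fractions matrix of control fractions, member CpGs in rows,
#'   controls in columns (pooled into one group).
#' @return two-sided p-value in `(0, 1]`.
#' @export
mwu_region_test <- function(tumor_fractions, control_fractions) {
  y <- as.vector(as.matrix(control_fractions))
  if (length(tumor_fractions) == 0L || length(y) == 0L)
    stopf("mwu_region_test: both groups must be non-empty")
  mwu_test(tumor_fractions, y)$p_value
}

#' Call differentially methylated regions (DMRs) for one tumor
#'
#' Composition of the pipeline core: control averaging, DMC calling,
#' consecutive-DMC segmentation and the region-level Mann-Whitney test.
#' Candidates with p below `alpha` are reported (optionally after
#' Benjamini-Hochberg correction across candidates when `config$fdr` is set).
#'
#' @param tumor a [methylome_sample()].
#' @param controls list of control [methylome_sample()]s (or a pre-computed
#'   `control_profile` via [call_dmrs_profiled()]).
#' @param config a [pipeline_config()].
#' @return data.table of DMRs: `chrom`, `start`, `end`, `direction`,
#'   `n_cpgs`, `mean_delta`, `p_value` (and `p_adjusted` when FDR is on).
#' @export
call_dmrs <- function(tumor, controls, config = pipeline_config()) {
  profile <- average_controls(controls, config)
  call_dmrs_profiled(tumor, profile, config)
}

#' @rdname call_dmrs
#' @param profile a `control_profile` from [average_controls()], reusable
#'   across tumors.
#' @export
call_dmrs_profiled <- function(tumor, profile, config = pipeline_config()) {
  dmcs <- call_dmcs(tumor, profile, config)
  cand <- segment_dmrs(dmcs, config)
  if (nrow(cand) == 0L) {
    return(data.table::data.table(
      chrom = character(), start = numeric(), end = numeric(),
      direction = character(), n_cpgs = integer(), mean_delta = numeric(),
      p_value = numeric()))
  }
  cand[, p_value := vapply(members, function(rows) {
    pr <- dmcs$profile_row[rows]
    mwu_region_test(dmcs$tumor_fraction[rows],
                    profile$fractions[pr, , drop = FALSE])
  }, numeric(1))]
  cand[, members := NULL]
  if (config$fdr) {
    cand[, p_adjusted := stats::p.adjust(p_value, method = "BH")]
    out <- cand[p_adjusted < config$alpha]
  } else {
    out <- cand[p_value < config$alpha]
  }
  data.table::setorder(out, chrom, start)
  out[]
}

#' Per-direction DMR counts
#'
#' Convenience tally mirroring per-tumor hypo/hyper bar charts.
#' @param dmrs a DMR table.
#' @return named integer vector with elements `hypo` and `hyper`.
#' @export
dmr_direction_counts <- function(dmrs) {
  c(hypo = sum(dmrs$direction == "hypo"),
    hyper = sum(dmrs$direction == "hyper"))
}
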