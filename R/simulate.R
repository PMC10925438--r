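#' Promoter window around a TSS
#'
#' The promoter is the strand-oriented window from `upstream` bp before to
#' `downstream` bp after the transcription start site, in 0-based half-open
#' coordinates. For a plus-strand TSS at 50,000 with the defaults this is
#' `[48500, 50500)`; for a minus-strand gene the window is reflected,
#' spanning `TSS - downstream .. TSS + upstream`.
#'
#' @param tss 0-based TSS position(s).
#' @param strand `"+"` or `"-"` (vectorized).
#' @param upstream,downstream window extent in bp (defaults 1500 / 500).
#' @return data.table with columns `start`, `end` (half-open).
#' @export
promoter_window <- function(tss, strand, upstream = 1500L, downstream = 500L) {
  if (!all(strand %in% c("+", "-")))
    stopf("promoter_window: strand must be '+' or '-'")
  plus <- strand == "+"
  data.table::data.table(
    start = ifelse(plus, tss - upstream, tss - downstream + 1L),
    end   = ifelse(plus, tss + downstream, tss + upstream + 1L))
}

#' Generate a synthetic genome: CpG sites, gene models, feature catalog
#'
#' Lays out strictly increasing CpG positions per chromosome (mean spacing
#' `cpg_spacing_mean`), places genes in evenly sized slots with random strand,
#' body length and exon/intron structure, and derives promoter windows from
#' each TSS. Enhancers are placed between gene slots; repeats are scattered
#' outside promoter windows. Every CpG receives a latent methylation fraction
#' from a three-compartment mixture, overridden inside promoters by the
#' gene's promoter state (high or low methylation).
#'
#' @param config a [sim_config()].
#' @return an object of class `dmr_genome`: list with `cpgs` (data.table
#'   `chrom`, `pos`, `latent`), `genes` (per-gene table incl. promoter window
#'   and state), `catalog` (a [feature_catalog()]) and the `config`.
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  spacing <- config$cpg_spacing_mean

  # ---- CpG positions -------------------------------------------------------
  cpgs <- data.table::rbindlist(lapply(chroms, function(ch) {
    n_draw <- ceiling(config$chrom_length / spacing * 1.3) + 50
    gaps <- 2L + stats::rgeom(n_draw, prob = 1 / max(spacing - 1, 1.01))
    pos <- 100L + cumsum(gaps)
    data.table::data.table(chrom = ch,
                           pos = as.integer(pos[pos < config$chrom_length - 100]))
  }))

  # ---- gene layout ---------------------------------------------------------
  n_per <- diff(round(seq(0, config$n_genes, length.out = config$n_chromosomes + 1)))
  margin <- 2500
  genes <- data.table::rbindlist(lapply(seq_along(chroms), function(ci) {
    ng <- n_per[ci]
    if (ng == 0L) return(NULL)
    slot <- (config$chrom_length - 2 * margin) / ng
    if (slot < 6000)
      stopf(paste0("generate_genome: chromosome %s too short to host %d genes ",
                   "(slot %.0f bp < 6000 bp needed for promoter + body)"),
            chroms[ci], ng, slot)
    out <- vector("list", ng)
    for (g in seq_len(ng)) {
      slot_start <- margin + (g - 1) * slot
      strand <- sample(c("+", "-"), 1L)
      body_len <- round(stats::runif(1, 2000, min(8000, slot * 0.6)))
      gene_start <- round(slot_start + stats::runif(1, 1600, slot * 0.3))
      gene_end <- gene_start + body_len
      tss <- if (strand == "+") gene_start else gene_end - 1L
      out[[g]] <- data.table::data.table(
        gene_id = sprintf("G%s_%03d", sub("chr", "", chroms[ci]), g),
        chrom = chroms[ci], strand = strand,
        gene_start = gene_start, gene_end = gene_end, tss = as.integer(tss))
    }
    data.table::rbindlist(out)
  }))
  pw <- promoter_window(genes$tss, genes$strand)
  genes[, `:=`(prom_start = pw$start, prom_end = pw$end)]
  if (any(genes$prom_start < 0) || any(genes$prom_end > config$chrom_length))
    stopf("generate_genome: a promoter window falls off the chromosome; increase chrom_length")

  # exon/intron structure: alternating pieces inside the gene body
  exint <- data.table::rbindlist(lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i]
    body <- g$gene_end - g$gene_start
    n_ex <- sample(3:6, 1L)
    ex_w <- round(stats::runif(n_ex, 100, 400))
    if (sum(ex_w) > 0.8 * body) ex_w <- floor(ex_w * 0.8 * body / sum(ex_w))
    rem <- body - sum(ex_w)
    cuts <- sort(stats::runif(n_ex - 2))
    in_w <- round(diff(c(0, cuts, 1)) * rem)
    widths <- integer(2 * n_ex - 1)
    widths[seq(1, 2 * n_ex - 1, by = 2)] <- ex_w
    widths[seq(2, 2 * n_ex - 2, by = 2)] <- in_w
    starts <- g$gene_start + cumsum(c(0L, widths[-length(widths)]))
    keep <- widths > 0
    data.table::data.table(
      chrom = g$chrom,
      start = starts[keep], end = (starts + widths)[keep],
      category = rep(c("exon", "intron"), length.out = length(widths))[keep],
      gene_id = g$gene_id, strand = g$strand)
  }))

  # enhancers midway between gene slots; repeats anywhere outside promoters
  enh <- data.table::rbindlist(lapply(seq_along(chroms), function(ci) {
    ng <- n_per[ci]
    n_enh <- max(1L, floor(ng / 2))
    slot <- (config$chrom_length - 2 * margin) / max(ng, 1)
    st <- round(margin + (sample(seq_len(max(ng, 1)), n_enh) - 0.15) * slot +
                  stats::runif(n_enh, -200, 200))
    w <- round(stats::runif(n_enh, 200, 800))
    data.table::data.table(chrom = chroms[ci],
                           start = pmax(st, 0),
                           end = pmin(st + w, config$chrom_length),
                           category = "enhancer",
                           gene_id = NA_character_, strand = ".")
  }))
  rep_try <- data.table::rbindlist(lapply(chroms, function(ch) {
    n_rep <- max(2L, round(config$n_genes / config$n_chromosomes))
    st <- round(stats::runif(3 * n_rep, 0, config$chrom_length - 1600))
    data.table::data.table(chrom = ch, start = st,
                           end = st + round(stats::runif(3 * n_rep, 200, 1500)),
                           category = "repeat",
                           gene_id = NA_character_, strand = ".")
  }))
  # keep repeats clear of all promoter windows (coupled genes are chosen later)
  pr <- genes[, .(chrom, start = prom_start, end = prom_end)]
  data.table::setkey(pr, chrom, start, end)
  ov <- data.table::foverlaps(
    data.table::setkey(data.table::copy(rep_try)[, .(chrom, start, end)],
                       chrom, start, end),
    pr, which = TRUE, nomatch = NULL)
  drop <- unique(ov$xid)
  reps <- if (length(drop)) rep_try[-drop] else rep_try
  reps <- reps[, utils::head(.SD, max(2L, round(config$n_genes / config$n_chromosomes))),
               by = chrom]

  catalog <- feature_catalog(data.table::rbindlist(list(
    genes[, .(chrom, start = prom_start, end = prom_end,
              category = "promoter", gene_id, strand)],
    exint, enh, reps), use.names = TRUE))

  # ---- promoter states and latent methylation ------------------------------
  # promoters span the methylation range: mostly high, a configurable low
  # fraction (highly expressed genes) and an intermediate fraction
  ng <- nrow(genes)
  n_low_prom <- round(config$frac_low_meth_promoters * ng)
  n_mid_prom <- round(config$frac_mid_meth_promoters * ng)
  states <- sample(c(rep("low", n_low_prom), rep("mid", n_mid_prom),
                     rep("high", ng - n_low_prom - n_mid_prom)))
  genes[, prom_state := states]
  genes[, prom_target := data.table::fifelse(
    prom_state == "low", config$baseline_low_meth,
    data.table::fifelse(prom_state == "high", config$baseline_high_meth,
                        stats::runif(ng, 0.28, 0.72)))]

  # methylation is regionally coherent: compartments are assigned in blocks
  # of consecutive CpGs (mean ~20 sites), each block drawing a latent mean
  n <- nrow(cpgs)
  conc <- config$latent_concentration
  n_blocks <- ceiling(n / 10)
  block_len <- 5L + stats::rgeom(n_blocks, 1 / 16)
  block_comp <- sample(c("high", "low", "mid"), n_blocks, replace = TRUE,
                       prob = c(1 - config$frac_low_cpgs - config$frac_mid_cpgs,
                                config$frac_low_cpgs, config$frac_mid_cpgs))
  block_mean <- ifelse(block_comp == "high", config$baseline_high_meth,
                       ifelse(block_comp == "low", config$baseline_low_meth,
                              stats::runif(n_blocks, 0.25, 0.75)))
  site_mean <- rep(block_mean, block_len)[seq_len(n)]
  cpgs[, latent := clamp(stats::rbeta(n, site_mean * conc,
                                      (1 - site_mean) * conc), 0.01, 0.99)]

  # promoter CpGs follow the gene's promoter state
  pq <- genes[, .(chrom, start = prom_start, end = prom_end, prom_target)]
  data.table::setkey(pq, chrom, start, end)
  site <- cpgs[, .(chrom, start = pos, end = pos + 1L, idx = .I)]
  data.table::setkey(site, chrom, start, end)
  hit <- data.table::foverlaps(site, pq, nomatch = NULL)
  if (nrow(hit)) {
    hit <- hit[!duplicated(idx)]   # overlapping promoters: first wins
    m <- hit$prom_target
    cpgs[hit$idx, latent := clamp(stats::rbeta(nrow(hit), m * conc,
                                               (1 - m) * conc),
                                  0.01, 0.99)]
  }

  # per-gene promoter latent mean (used by the expression simulator)
  pm <- data.table::foverlaps(site, pq, nomatch = NULL)
  if (nrow(pm)) {
    lat <- cpgs$latent
    pml <- pm[, .(prom_meth = mean(lat[idx])),
              by = .(chrom, start, end)]
    genes[pml, on = c(chrom = "chrom", prom_start = "start", prom_end = "end"),
          prom_meth := i.prom_meth]
  }
  genes[is.na(prom_meth), prom_meth := prom_target]
  genes[, length_bp := {
    ex <- exint[category == "exon"]
    v <- ex[, .(len = sum(end - start)), by = gene_id]
    v$len[match(gene_id, v$gene_id)]
  }]
  genes[is.na(length_bp) | length_bp < 100, length_bp := 1000]

  structure(list(cpgs = cpgs[], genes = genes[], catalog = catalog,
                 config = config),
            class = "dmr_genome")
}

#' @export
print.dmr_genome <- function(x, ...) {
  cat(sprintf("<dmr_genome> %d CpGs on %d chromosome(s), %d genes, %d features\n",
              nrow(x$cpgs), x$config$n_chromosomes, nrow(x$genes),
              nrow(x$catalog)))
  invisible(x)
}

# find the start indices (into `pos`) of runs of `width` consecutive CpGs with
# all inter-CpG gaps < max_gap and all latents satisfying `ok`
find_runs <- function(pos, ok, width, max_gap = 100) {
  n <- length(pos)
  if (n < width) return(integer())
  gap_ok <- c(diff(pos) < max_gap, FALSE)
  good <- ok & c(rep(TRUE, n))
  # window starting at i is valid if sites i..i+width-1 are good and
  # gaps i..i+width-2 are all < max_gap
  valid <- rep(TRUE, n - width + 1L)
  for (k in 0:(width - 1L)) valid <- valid & good[seq_len(n - width + 1L) + k]
  for (k in 0:(width - 2L)) valid <- valid & gap_ok[seq_len(n - width + 1L) + k]
  which(valid)
}

#' Plant differential methylation truth into a genome
#'
#' Chooses coupled genes (expression inversely tied to a planted promoter
#' region) and background regions, assigns carrier tumors to every planted
#' region, and returns a machine-readable truth set for recovery scoring.
#' Hypomethylated regions are placed on runs of highly methylated CpGs (so the
#' negative shift does not clamp), hypermethylated regions on lowly methylated
#' runs; all runs have inter-CpG gaps under 100 bp and planted regions never
#' overlap. The first coupled hypomethylated gene is guaranteed the
#' "promoter DMR in 6 of 7 tumors, expression up in 9 of 10" configuration.
#'
#' @param config a [sim_config()].
#' @param genome a `dmr_genome` from [generate_genome()].
#' @return an object of class `truth_set`: list with `planted_dmrs`
#'   (region_id, chrom, start, end, direction, effect, n_cpgs, gene_id,
#'   carriers, cpg_idx), `coupled_genes` (gene_id, region_id, direction,
#'   fold_change, expr_carriers) and `seed`.
#' @export
plant_truth <- function(config, genome) {
  set.seed(config$seed + 101L)
  cpgs <- genome$cpgs
  genes <- genome$genes
  eff <- config$planted_effect
  w <- config$planted_width_cpgs

  n_coupled <- round(config$coupled_gene_fraction * config$n_genes)
  n_coup_hyper <- round(n_coupled * config$coupled_hyper_fraction)
  n_coup_hypo <- n_coupled - n_coup_hyper
  if (n_coup_hypo > config$n_planted_hypo)
    stopf("plant_truth: %d coupled hypo genes need n_planted_hypo >= %d",
          n_coup_hypo, n_coup_hypo)
  if (n_coup_hyper > config$n_planted_hyper)
    stopf("plant_truth: %d coupled hyper genes need n_planted_hyper >= %d",
          n_coup_hyper, n_coup_hyper)

  # promoter CpG indices per gene
  pq <- genes[, .(chrom, start = prom_start, end = prom_end, gene_id)]
  data.table::setkey(pq, chrom, start, end)
  site <- cpgs[, .(chrom, start = pos, end = pos + 1L, idx = .I)]
  data.table::setkey(site, chrom, start, end)
  prom_sites <- data.table::foverlaps(site, pq, nomatch = NULL)
  prom_idx_by_gene <- split(prom_sites$idx, prom_sites$gene_id)
  in_promoter <- rep(FALSE, nrow(cpgs))
  in_promoter[prom_sites$idx] <- TRUE

  lat <- cpgs$latent
  taken <- rep(FALSE, nrow(cpgs))

  promoter_run <- function(gene_id, direction) {
    idx <- sort(prom_idx_by_gene[[gene_id]] %||% integer())
    if (length(idx) < w) return(NULL)
    ok <- if (direction == "hypo") lat[idx] >= eff + 0.05
          else lat[idx] <= 1 - eff - 0.05
    ok <- ok & !taken[idx]
    # indices must also be consecutive in the genome-wide site order
    consec <- c(diff(idx) == 1L, FALSE)
    starts <- find_runs(cpgs$pos[idx], ok, w)
    starts <- starts[vapply(starts, function(s) all(consec[s:(s + w - 2L)]),
                            logical(1))]
    if (!length(starts)) return(NULL)
    idx[starts[1] + 0:(w - 1L)]
  }

  # ---- coupled genes -------------------------------------------------------
  pick_genes <- function(state, need, direction) {
    cand <- genes[prom_state == state]$gene_id
    cand <- cand[order(match(cand, genes$gene_id))]
    cand <- sample(cand)                      # deterministic under the seed
    chosen <- list()
    for (g in cand) {
      if (length(chosen) == need) break
      run <- promoter_run(g, direction)
      if (!is.null(run)) {
        chosen[[g]] <- run
        taken[run] <<- TRUE
      }
    }
    if (length(chosen) < need)
      stopf(paste0("plant_truth: only %d of %d requested coupled %s genes have a ",
                   "promoter run of %d CpGs with gaps < 100 bp; enlarge the ",
                   "genome or reduce coupling"),
            length(chosen), need, direction, w)
    chosen
  }
  hypo_genes <- if (n_coup_hypo) pick_genes("high", n_coup_hypo, "hypo") else list()
  hyper_genes <- if (n_coup_hyper) pick_genes("low", n_coup_hyper, "hyper") else list()

  # ---- background regions (outside promoters) ------------------------------
  pick_background <- function(direction, need) {
    ok <- !in_promoter & !taken &
      (if (direction == "hypo") lat >= eff + 0.05 else lat <= 1 - eff - 0.05)
    out <- list()
    for (ch in unique(cpgs$chrom)) {
      sel <- which(cpgs$chrom == ch)
      starts <- find_runs(cpgs$pos[sel], ok[sel], w)
      starts <- sample(starts)
      for (s in starts) {
        if (length(out) == need) break
        run <- sel[s + 0:(w - 1L)]
        if (any(taken[run])) next
        # keep planted regions separated by at least one free CpG
        lo <- max(min(run) - 1L, 1L); hi <- min(max(run) + 1L, nrow(cpgs))
        if (any(taken[lo:hi])) next
        out[[length(out) + 1L]] <- run
        taken[run] <<- TRUE
      }
      if (length(out) == need) break
    }
    if (length(out) < need)
      stopf("plant_truth: could not place %d background %s regions (found %d); enlarge the genome",
            need, direction, length(out))
    out
  }
  n_bg_hypo <- config$n_planted_hypo - n_coup_hypo
  n_bg_hyper <- config$n_planted_hyper - n_coup_hyper
  bg_hypo <- if (n_bg_hypo) pick_background("hypo", n_bg_hypo) else list()
  bg_hyper <- if (n_bg_hyper) pick_background("hyper", n_bg_hyper) else list()

  runs <- c(hypo_genes, bg_hypo, hyper_genes, bg_hyper)
  direction <- c(rep("hypo", n_coup_hypo + n_bg_hypo),
                 rep("hyper", n_coup_hyper + n_bg_hyper))
  gene_ids <- c(names(hypo_genes) %||% character(),
                rep(NA_character_, n_bg_hypo),
                names(hyper_genes) %||% character(),
                rep(NA_character_, n_bg_hyper))
  n_regions <- length(runs)

  # ---- carrier schedule ----------------------------------------------------
  nt <- config$n_tumors
  if (!is.null(config$recurrence_schedule)) {
    carriers <- lapply(config$recurrence_schedule, as.integer)
  } else {
    coupled_flag <- !is.na(gene_ids)
    carriers <- vector("list", n_regions)
    ci <- 0L
    for (i in seq_len(n_regions)) {
      if (coupled_flag[i]) {
        ci <- ci + 1L
        carriers[[i]] <-
          if (ci %% 2L == 1L) setdiff(seq_len(nt), 1L + (ci %% nt)) # 6 of 7
          else seq_len(nt)                                          # all
      } else {
        k <- i %% 3L
        carriers[[i]] <- if (k == 1L) seq_len(nt)
          else if (k == 2L) setdiff(seq_len(nt), 1L + (i %% nt))
          else sort(sample(nt, sample(seq_len(max(1L, min(4L, nt - 1L))), 1L)))
      }
    }
  }

  planted <- data.table::data.table(
    region_id = sprintf("R%03d", seq_len(n_regions)),
    chrom = cpgs$chrom[vapply(runs, min, integer(1))],
    start = cpgs$pos[vapply(runs, min, integer(1))],
    end = cpgs$pos[vapply(runs, max, integer(1))] + 1L,
    direction = direction,
    effect = eff,
    n_cpgs = w,
    gene_id = gene_ids,
    carriers = carriers,
    cpg_idx = runs)

  # expression carriers: first coupled hypo gene gets 9 of 10, others alternate
  net <- config$n_expression_tumors
  coupled <- planted[!is.na(gene_id)]
  coupled_genes <- if (nrow(coupled)) {
    data.table::data.table(
      gene_id = coupled$gene_id,
      region_id = coupled$region_id,
      direction = coupled$direction,
      fold_change = config$fold_change_coupled,
      expr_carriers = lapply(seq_len(nrow(coupled)), function(i) {
        if (i %% 2L == 1L) setdiff(seq_len(net), 1L + (i %% net))
        else seq_len(net)
      }))
  } else {
    data.table::data.table(gene_id = character(), region_id = character(),
                           direction = character(), fold_change = numeric(),
                           expr_carriers = list())
  }

  structure(list(planted_dmrs = planted, coupled_genes = coupled_genes,
                 seed = config$seed),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> %d planted regions (%d hypo / %d hyper), %d coupled genes, seed %s\n",
              nrow(x$planted_dmrs),
              sum(x$planted_dmrs$direction == "hypo"),
              sum(x$planted_dmrs$direction == "hyper"),
              nrow(x$coupled_genes), x$seed))
  invisible(x)
}

#' Simulate WGBS methylomes
#'
#' Draws, per sample and CpG, a depth from a Poisson law truncated at 1 and a
#' methylated count from a binomial around the site's latent fraction.
#' Controls share latent fractions up to a small per-control perturbation;
#' tumors receive independent baseline noise and, inside planted regions they
#' carry, a latent shift of minus (hypo) or plus (hyper) the planted effect,
#' clamped to `[0.001, 0.999]`.
#'
#' @param config a [sim_config()].
#' @param genome a `dmr_genome`.
#' @param truth a `truth_set`; every planted region must sit on CpGs of
#'   `genome` (a mismatch is a consistency error).
#' @return named list of [methylome_sample()]s: `ctrl_1..n`, then
#'   `tumor_1..m`.
#' @export
simulate_methylomes <- function(config, genome, truth) {
  cpgs <- genome$cpgs
  # consistency: planted regions must lie on simulated CpGs
  key <- paste(cpgs$chrom, cpgs$pos)
  for (i in seq_len(nrow(truth$planted_dmrs))) {
    idx <- truth$planted_dmrs$cpg_idx[[i]]
    r <- truth$planted_dmrs[i]
    if (is.null(idx)) {
      # truth restored from disk: recover indices from coordinates
      idx <- which(cpgs$chrom == r$chrom & cpgs$pos >= r$start &
                     cpgs$pos < r$end)
      if (length(idx) < r$n_cpgs)
        stopf("simulate_methylomes: planted region %s does not lie on simulated CpGs",
              r$region_id)
      truth$planted_dmrs$cpg_idx[[i]] <- idx
    } else if (any(idx < 1L | idx > nrow(cpgs)) ||
               !all(paste(r$chrom, cpgs$pos[range(idx)]) %in% key) ||
               cpgs$pos[min(idx)] != r$start || cpgs$pos[max(idx)] + 1L != r$end) {
      stopf("simulate_methylomes: truth/position mismatch for region %s",
            r$region_id)
    }
  }

  set.seed(config$seed + 202L)
  n <- nrow(cpgs)
  draw <- function(latent, noise_sd) {
    d <- stats::rpois(n, config$depth_mean)
    d[d < 1L] <- 1L
    p <- clamp(latent + stats::rnorm(n, 0, noise_sd), 0.001, 0.999)
    m <- stats::rbinom(n, d, p)
    data.table::data.table(chrom = cpgs$chrom, pos = cpgs$pos,
                           count_meth = m, count_total = d)
  }

  out <- list()
  for (i in seq_len(config$n_controls)) {
    out[[sprintf("ctrl_%d", i)]] <-
      methylome_sample(sprintf("ctrl_%d", i),
                       draw(cpgs$latent, config$control_noise_sd))
  }
  for (j in seq_len(config$n_tumors)) {
    shift <- numeric(n)
    pd <- truth$planted_dmrs
    for (i in seq_len(nrow(pd))) {
      if (j %in% pd$carriers[[i]]) {
        s <- if (pd$direction[i] == "hypo") -pd$effect[i] else pd$effect[i]
        shift[pd$cpg_idx[[i]]] <- s
      }
    }
    out[[sprintf("tumor_%d", j)]] <-
      methylome_sample(sprintf("tumor_%d", j),
                       draw(clamp(cpgs$latent + shift, 0.001, 0.999),
                            config$tumor_noise_sd))
  }
  out
}

#' Simulate an expression count matrix with gene lengths
#'
#' Per-gene baseline mean FPKM follows the inverse promoter-methylation
#' coupling `fpkm_scale * 2^(expression_coupling * (1 - m))` (m = promoter
#' latent methylation) with lognormal gene-level noise. Expected counts scale
#' with gene length (summed exons, kb) and library size (millions); counts
#' are negative binomial with the configured dispersion. Coupled genes have
#' their mean multiplied by `fold_change_coupled` (hypomethylated promoter,
#' expression up) or divided by it (hypermethylated, down) in carrier tumors.
#'
#' @param config a [sim_config()].
#' @param genome a `dmr_genome`.
#' @param truth a `truth_set` whose coupled genes exist in the genome.
#' @return list with `counts` (genes x samples integer matrix; columns
#'   `ectrl_*` then `etumor_*`), `lengths` (named bp vector),
#'   `mu_fpkm` (latent per-gene baseline FPKM) and `library_sizes`.
#' @export
simulate_expression <- function(config, genome, truth) {
  genes <- genome$genes
  if (nrow(truth$coupled_genes) &&
      !all(truth$coupled_genes$gene_id %in% genes$gene_id))
    stopf("simulate_expression: coupled genes missing from the genome")

  set.seed(config$seed + 303L)
  ng <- nrow(genes)
  nc <- config$n_expression_controls
  nt <- config$n_expression_tumors
  samples <- c(sprintf("ectrl_%d", seq_len(nc)), sprintf("etumor_%d", seq_len(nt)))

  mu_fpkm <- config$fpkm_scale *
    2^(config$expression_coupling * (1 - genes$prom_meth)) *
    exp(stats::rnorm(ng, 0, config$gene_noise_sd))
  lib <- round(config$library_size_mean * stats::runif(nc + nt, 0.85, 1.15))

  mu <- outer(mu_fpkm * genes$length_bp / 1000, lib / 1e6)
  cg <- truth$coupled_genes
  for (i in seq_len(nrow(cg))) {
    gi <- match(cg$gene_id[i], genes$gene_id)
    cols <- nc + cg$expr_carriers[[i]]
    fac <- if (cg$direction[i] == "hypo") cg$fold_change[i] else 1 / cg$fold_change[i]
    mu[gi, cols] <- mu[gi, cols] * fac
  }

  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$expression_dispersion),
                   nrow = ng, dimnames = list(genes$gene_id, samples))
  list(counts = counts,
       lengths = stats::setNames(as.numeric(genes$length_bp), genes$gene_id),
       mu_fpkm = stats::setNames(mu_fpkm, genes$gene_id),
       library_sizes = stats::setNames(lib, samples))
}

#' Run the whole simulator
#'
#' Convenience wrapper: genome, truth, methylomes and expression in one call.
#'
#' @param config a [sim_config()].
#' @return list with elements `genome`, `truth`, `methylomes`, `expression`.
#' @export
simulate_all <- function(config) {
  genome <- generate_genome(config)
  truth <- plant_truth(config, genome)
  methylomes <- simulate_methylomes(config, genome, truth)
  expression <- simulate_expression(config, genome, truth)
  list(genome = genome, truth = truth, methylomes = methylomes,
       expression = expression)
}
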