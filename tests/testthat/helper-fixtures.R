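# shared fixture builders; everything is generated in code, no data files

# a minimal genome configuration that still hosts planted regions
tiny_sim_config <- function(seed = 1L, ...) {
  sim_config(n_chromosomes = 1L, chrom_length = 2e5, n_genes = 20L,
             n_planted_hypo = 4L, n_planted_hyper = 2L,
             coupled_gene_fraction = 0.1, seed = seed, ...)
}

# build a methylome sample from vectors (depth defaults to 20x everywhere)
make_sample <- function(id, pos, frac, depth = 20L, chrom = "chr1") {
  depth <- rep_len(depth, length(pos))
  methylome_sample(id, data.frame(
    chrom = chrom, pos = pos,
    count_meth = as.integer(round(frac * depth)),
    count_total = as.integer(depth)))
}

# brute-force two-sided exact MWU p-value by enumerating all rank splits
mwu_brute_force <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  splits <- utils::combn(m + n, m)
  us <- apply(splits, 2, function(idx) sum(seq_len(m + n)[idx]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# brute-force per-base recurrence: maximal intervals where >= n_required tumors
# have a same-direction DMR covering the base
recurrence_brute_force <- function(dmr_list, n_required, dir, chrom = "chr1") {
  lo <- min(vapply(dmr_list, function(d) {
    d <- d[d$direction == dir & d$chrom == chrom, ]
    if (nrow(d)) min(d$start) else Inf
  }, numeric(1)))
  hi <- max(vapply(dmr_list, function(d) {
    d <- d[d$direction == dir & d$chrom == chrom, ]
    if (nrow(d)) max(d$end) else -Inf
  }, numeric(1)))
  if (!is.finite(lo)) return(data.frame(start = numeric(), end = numeric()))
  bases <- lo:(hi - 1)
  depth <- vapply(bases, function(b) {
    sum(vapply(dmr_list, function(d) {
      d <- d[d$direction == dir & d$chrom == chrom, ]
      any(d$start <= b & b < d$end)
    }, logical(1)))
  }, numeric(1))
  in_core <- depth >= n_required
  if (!any(in_core)) return(data.frame(start = numeric(), end = numeric()))
  runs <- rle(in_core)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  keep <- runs$values
  data.frame(start = bases[starts[keep]], end = bases[ends[keep]] + 1)
}

# overlap-based matching of called DMRs against planted truth
match_planted <- function(dmrs, planted) {
  is_true <- vapply(seq_len(nrow(dmrs)), function(i) {
    any(planted$chrom == dmrs$chrom[i] & planted$start < dmrs$end[i] &
          planted$end > dmrs$start[i] & planted$direction == dmrs$direction[i])
  }, logical(1))
  recovered <- vapply(seq_len(nrow(planted)), function(i) {
    any(dmrs$chrom == planted$chrom[i] & dmrs$start < planted$end[i] &
          dmrs$end > planted$start[i] & dmrs$direction == planted$direction[i])
  }, logical(1))
  list(true_positive = sum(is_true), false_positive = sum(!is_true),
       recovered = sum(recovered), planted = nrow(planted))
}

# a small deterministic feature catalog used across annotation tests
toy_catalog <- function() {
  feature_catalog(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(1000, 1100, 3000, 5000, 5200, 100),
    end = c(3000, 1500, 4000, 5400, 5600, 900),
    category = c("promoter", "repeat", "intron", "exon", "exon", "enhancer"),
    gene_id = c("GA", NA, "GA", "GB", "GB", NA),
    strand = c("+", ".", "+", "-", "-", ".")))
}
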