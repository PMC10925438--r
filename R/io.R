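#' Methylome sample container
#'
#' Per-sample, position-sorted per-CpG methylation calls. Coordinates are
#' 0-based positions of the CpG dinucleotide (strands pre-merged); one record
#' per CpG.
#'
#' @param sample_id sample identifier.
#' @param records data.frame/data.table with columns `chrom`, `pos`,
#'   `count_meth`, `count_total`.
#' @return a `methylome_sample`: a data.table with attribute `sample_id`.
#' @export
methylome_sample <- function(sample_id, records) {
  dt <- data.table::as.data.table(records)
  need <- c("chrom", "pos", "count_meth", "count_total")
  if (!all(need %in% names(dt)))
    stopf("methylome_sample: records must have columns %s",
          paste(need, collapse = ", "))
  dt <- dt[, need, with = FALSE]
  dt[, `:=`(chrom = as.character(chrom), pos = as.integer(pos),
            count_meth = as.integer(count_meth),
            count_total = as.integer(count_total))]
  if (nrow(dt)) {
    if (any(dt$count_meth < 0L) || any(dt$count_total < 0L))
      stopf("methylome_sample: negative counts")
    if (any(dt$count_meth > dt$count_total))
      stopf("methylome_sample: count_meth exceeds count_total")
    data.table::setorder(dt, chrom, pos)
    dup <- dt[, any(duplicated(pos)), by = chrom]$V1
    if (any(dup))
      stopf("methylome_sample: duplicated positions within a chromosome")
  }
  data.table::setattr(dt, "sample_id", as.character(sample_id))
  data.table::setattr(dt, "class",
                      c("methylome_sample", class(data.table::data.table())))
  dt
}

#' @export
print.methylome_sample <- function(x, ...) {
  cat(sprintf("<methylome_sample> %s: %d CpG records on %d chromosome(s)\n",
              attr(x, "sample_id"), nrow(x),
              data.table::uniqueN(x$chrom)))
  if (nrow(x)) print(utils::head(data.table::as.data.table(x), 5))
  invisible(x)
}

#' Sample identifier of a methylome
#' @param x a `methylome_sample`.
#' @return character scalar.
#' @export
sample_id <- function(x) attr(x, "sample_id")

#' Per-CpG methylation fraction
#'
#' `count_meth / count_total`; defined only for covered sites (the container
#' forbids nothing, but uncovered sites yield `NaN`).
#' @param x a `methylome_sample`.
#' @return numeric vector aligned with the records.
#' @export
meth_fraction <- function(x) x$count_meth / x$count_total

#' Feature catalog container
#'
#' Strand-aware genomic intervals (0-based, half-open) labeled with one of the
#' categories promoter / enhancer / exon / intron / repeat, optionally carrying
#' a gene identifier. Promoter intervals must carry a gene id and an oriented
#' strand.
#'
#' @param intervals data.frame/data.table with columns `chrom`, `start`,
#'   `end`, `category`, and optionally `gene_id`, `strand`.
#' @return a `feature_catalog` data.table.
#' @export
feature_catalog <- function(intervals) {
  dt <- data.table::as.data.table(intervals)
  need <- c("chrom", "start", "end", "category")
  if (!all(need %in% names(dt)))
    stopf("feature_catalog: intervals must have columns %s",
          paste(need, collapse = ", "))
  if (!"gene_id" %in% names(dt)) dt[, gene_id := NA_character_]
  if (!"strand" %in% names(dt)) dt[, strand := "."]
  dt <- dt[, c("chrom", "start", "end", "category", "gene_id", "strand"),
           with = FALSE]
  dt[, `:=`(chrom = as.character(chrom), start = as.numeric(start),
            end = as.numeric(end), category = as.character(category),
            gene_id = as.character(gene_id), strand = as.character(strand))]
  if (nrow(dt)) {
    if (any(dt$start >= dt$end))
      stopf("feature_catalog: start must be < end for every interval")
    bad <- setdiff(unique(dt$category), FEATURE_CATEGORIES)
    if (length(bad))
      stopf("feature_catalog: unknown categories: %s", paste(bad, collapse = ", "))
    if (!all(dt$strand %in% c("+", "-", ".")))
      stopf("feature_catalog: strand must be one of '+', '-', '.'")
    prom <- dt[category == "promoter"]
    if (nrow(prom) && (anyNA(prom$gene_id) || any(!prom$strand %in% c("+", "-"))))
      stopf("feature_catalog: promoter intervals need gene_id and oriented strand")
  }
  data.table::setattr(dt, "class",
                      c("feature_catalog", class(data.table::data.table())))
  dt
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat(sprintf("<feature_catalog> %d intervals\n", nrow(x)))
  if (nrow(x)) print(x[, .N, by = category])
  invisible(x)
}

# ---- Bismark-style coverage files -----------------------------------------

#' Read a Bismark-style coverage file
#'
#' Six tab-separated columns: chromosome, start, end, percent methylation,
#' count methylated, count unmethylated. Columns 2 and 3 follow Bismark's
#' 1-based inclusive convention and are converted to 0-based positions
#' internally. The percent column is cross-checked against the counts and a
#' disagreement beyond 0.5 percentage points is an error, not a repair.
#'
#' @param path file path (plain or gzipped TSV).
#' @param sample_id sample identifier; defaults to the file name without
#'   extensions.
#' @return a [methylome_sample()].
#' @export
read_bismark_coverage <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stopf("read_bismark_coverage: no such file: %s", path)
  if (is.null(sample_id))
    sample_id <- sub("\\..*$", "", basename(path))
  dt <- suppressWarnings(
    data.table::fread(path, header = FALSE, sep = "\t",
                      colClasses = "character", fill = TRUE))
  if (nrow(dt) == 0L) {
    warnf("read_bismark_coverage: %s is empty; returning an empty sample", path)
    return(methylome_sample(sample_id, data.table::data.table(
      chrom = character(), pos = integer(),
      count_meth = integer(), count_total = integer())))
  }
  if (ncol(dt) != 6L)
    stopf("read_bismark_coverage: expected 6 tab-separated columns, found %d",
          ncol(dt))
  data.table::setnames(dt, c("chrom", "start", "end", "pct", "cm", "cu"))
  num <- suppressWarnings(data.table::data.table(
    start = as.numeric(dt$start), end = as.numeric(dt$end),
    pct = as.numeric(dt$pct), cm = as.numeric(dt$cm), cu = as.numeric(dt$cu)))
  bad <- which(!stats::complete.cases(num))
  if (length(bad))
    stopf("read_bismark_coverage: malformed line %d in %s", bad[1], path)
  bad <- which(num$cm != floor(num$cm) | num$cu != floor(num$cu) |
                 num$cm < 0 | num$cu < 0)
  if (length(bad))
    stopf("read_bismark_coverage: non-integer or negative counts at line %d",
          bad[1])
  tot <- num$cm + num$cu
  chk <- which(tot > 0 & abs(num$pct - 100 * num$cm / tot) > 0.5)
  if (length(chk))
    stopf(paste0("read_bismark_coverage: percent column disagrees with counts",
                 " at line %d (%.1f%% vs %.1f%%)"),
          chk[1], num$pct[chk[1]], 100 * num$cm[chk[1]] / tot[chk[1]])
  methylome_sample(sample_id, data.table::data.table(
    chrom = dt$chrom,
    pos = as.integer(num$start - 1),   # 1-based inclusive -> 0-based
    count_meth = as.integer(num$cm),
    count_total = as.integer(tot)))
}

#' Write a Bismark-style coverage file
#'
#' Inverse of [read_bismark_coverage()]: positions are emitted 1-based
#' inclusive and the percent column is recomputed from the counts.
#'
#' @param sample a [methylome_sample()] with covered sites only.
#' @param path output path (`.gz` is compressed).
#' @export
write_bismark_coverage <- function(sample, path) {
  if (any(sample$count_total < 1L))
    stopf("write_bismark_coverage: uncovered sites cannot be serialized")
  out <- data.table::data.table(
    chrom = sample$chrom,
    start = sample$pos + 1L,
    end = sample$pos + 1L,
    pct = round(100 * sample$count_meth / sample$count_total, 6),
    cm = sample$count_meth,
    cu = sample$count_total - sample$count_meth)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Export methylation fractions as bedGraph
#'
#' One line per covered CpG with the methylation percentage, suitable for
#' genome browsers.
#'
#' @param sample a [methylome_sample()].
#' @param path output path.
#' @export
write_bedgraph <- function(sample, path) {
  out <- data.table::data.table(
    chrom = sample$chrom, start = sample$pos, end = sample$pos + 1L,
    value = round(100 * sample$count_meth / pmax(sample$count_total, 1L), 4))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# ---- BED -------------------------------------------------------------------

#' Read a BED3/BED6 file into a feature catalog fragment
#'
#' @param path BED file path.
#' @param category feature category to tag every interval with (one of
#'   promoter, enhancer, exon, intron, repeat).
#' @return a [feature_catalog()] fragment. BED3 rows get strand `"."` and no
#'   gene id; overlapping intervals are kept as-is (no merging).
#' @export
read_bed <- function(path, category) {
  if (!file.exists(path)) stopf("read_bed: no such file: %s", path)
  if (!category %in% FEATURE_CATEGORIES)
    stopf("read_bed: category must be one of %s",
          paste(FEATURE_CATEGORIES, collapse = ", "))
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (nrow(dt) == 0L)
    return(feature_catalog(data.table::data.table(
      chrom = character(), start = numeric(), end = numeric(),
      category = character(), gene_id = character(), strand = character())))
  if (ncol(dt) < 3L) stopf("read_bed: %s is not BED3/BED6", path)
  out <- data.table::data.table(
    chrom = as.character(dt[[1]]),
    start = as.numeric(dt[[2]]),
    end = as.numeric(dt[[3]]),
    category = category,
    gene_id = if (ncol(dt) >= 4L) as.character(dt[[4]]) else NA_character_,
    strand = if (ncol(dt) >= 6L) as.character(dt[[6]]) else ".")
  if (any(out$start >= out$end))
    stopf("read_bed: start >= end at line %d", which(out$start >= out$end)[1])
  feature_catalog(out)
}

#' Write a feature catalog (or fragment) as BED6
#' @param catalog a [feature_catalog()].
#' @param path output path.
#' @export
write_bed <- function(catalog, path) {
  out <- data.table::data.table(
    chrom = catalog$chrom, start = catalog$start, end = catalog$end,
    name = data.table::fifelse(is.na(catalog$gene_id), ".", catalog$gene_id),
    score = 0L, strand = catalog$strand)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# ---- DMR tables ------------------------------------------------------------

dmr_columns <- c("chrom", "start", "end", "direction", "n_cpgs",
                 "mean_delta", "p_value")

#' Write / read called DMRs
#'
#' BED-like TSV with a header line: chrom, start, end, direction, n_cpgs,
#' mean_delta, p_value. p-values survive a round trip to within 1e-15
#' relative.
#'
#' @param dmrs a DMR table as returned by [call_dmrs()].
#' @param path file path.
#' @return `read_dmrs` returns the DMR data.table.
#' @export
write_dmrs <- function(dmrs, path) {
  dt <- data.table::as.data.table(dmrs)
  if (!all(dmr_columns %in% names(dt)))
    stopf("write_dmrs: missing columns: %s",
          paste(setdiff(dmr_columns, names(dt)), collapse = ", "))
  data.table::fwrite(dt[, dmr_columns, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' @rdname write_dmrs
#' @export
read_dmrs <- function(path) {
  if (!file.exists(path)) stopf("read_dmrs: no such file: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!all(dmr_columns %in% names(dt)))
    stopf("read_dmrs: %s lacks the DMR header", path)
  if (nrow(dt) && !all(dt$direction %in% c("hypo", "hyper")))
    stopf("read_dmrs: direction must be 'hypo' or 'hyper'")
  dt[, `:=`(chrom = as.character(chrom), start = as.numeric(start),
            end = as.numeric(end), n_cpgs = as.integer(n_cpgs))]
  dt[]
}

# ---- count matrices and gene lengths ---------------------------------------

#' Read a gene-level count matrix
#'
#' TSV with a `gene_id` column followed by one column per sample. Duplicate
#' gene ids and missing cells are errors.
#'
#' @param path file path.
#' @return numeric matrix, genes in rows (named), samples in columns.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stopf("read_counts: no such file: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!"gene_id" %in% names(dt))
    stopf("read_counts: first column must be 'gene_id'")
  if (anyDuplicated(dt$gene_id))
    stopf("read_counts: duplicate gene ids (e.g. %s)",
          dt$gene_id[duplicated(dt$gene_id)][1])
  samples <- setdiff(names(dt), "gene_id")
  if (!length(samples)) stopf("read_counts: no sample columns")
  m <- as.matrix(dt[, samples, with = FALSE])
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stopf("read_counts: missing cell at gene %s, sample %s",
          dt$gene_id[idx[1]], samples[idx[2]])
  }
  if (!is.numeric(m)) stopf("read_counts: non-numeric cells present")
  rownames(m) <- dt$gene_id
  m
}

#' Write a gene-level count matrix
#' @param counts numeric matrix with gene rownames.
#' @param path file path.
#' @export
write_counts <- function(counts, path) {
  if (is.null(rownames(counts))) stopf("write_counts: counts need gene rownames")
  dt <- data.table::data.table(gene_id = rownames(counts))
  dt <- cbind(dt, data.table::as.data.table(counts))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read / write gene lengths
#'
#' Two-column TSV (`gene_id`, `length`); lengths are bp of summed exons.
#' @param path file path.
#' @return named numeric vector of lengths.
#' @export
read_gene_lengths <- function(path) {
  if (!file.exists(path)) stopf("read_gene_lengths: no such file: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!all(c("gene_id", "length") %in% names(dt)))
    stopf("read_gene_lengths: need columns gene_id, length")
  if (anyDuplicated(dt$gene_id)) stopf("read_gene_lengths: duplicate gene ids")
  if (any(dt$length <= 0)) stopf("read_gene_lengths: lengths must be positive")
  stats::setNames(as.numeric(dt$length), dt$gene_id)
}

#' @rdname read_gene_lengths
#' @param lengths named numeric vector.
#' @export
write_gene_lengths <- function(lengths, path) {
  data.table::fwrite(
    data.table::data.table(gene_id = names(lengths),
                           length = as.numeric(lengths)),
    path, sep = "\t")
  invisible(path)
}

# ---- truth tables ----------------------------------------------------------

#' Serialize / restore a simulation truth set
#'
#' Two TSVs are written: `<prefix>.regions.tsv` (planted regions with their
#' carrier tumors, comma-joined) and `<prefix>.genes.tsv` (coupled genes). The
#' round trip is lossless.
#'
#' @param truth a `truth_set` from [plant_truth()].
#' @param prefix output path prefix.
#' @return `read_truth` returns the restored `truth_set`.
#' @export
write_truth <- function(truth, prefix) {
  reg <- data.table::copy(truth$planted_dmrs)
  reg[, carriers := vapply(carriers, paste, character(1), collapse = ",")]
  if ("cpg_idx" %in% names(reg)) reg[, cpg_idx := NULL]
  reg[, seed := truth$seed]
  data.table::fwrite(reg, paste0(prefix, ".regions.tsv"), sep = "\t", na = "NA")
  gen <- data.table::copy(truth$coupled_genes)
  gen[, expr_carriers := vapply(expr_carriers, paste, character(1),
                                collapse = ",")]
  data.table::fwrite(gen, paste0(prefix, ".genes.tsv"), sep = "\t", na = "NA")
  invisible(prefix)
}

#' @rdname write_truth
#' @export
read_truth <- function(prefix) {
  reg <- data.table::fread(paste0(prefix, ".regions.tsv"), sep = "\t",
                           colClasses = list(character = "carriers"))
  seed <- if (nrow(reg)) as.integer(reg$seed[1]) else NA_integer_
  if ("seed" %in% names(reg)) reg[, seed := NULL]
  reg[, carriers := lapply(strsplit(as.character(carriers), ","), as.integer)]
  gen <- data.table::fread(paste0(prefix, ".genes.tsv"), sep = "\t",
                           colClasses = list(character = "expr_carriers"))
  gen[, expr_carriers := lapply(strsplit(as.character(expr_carriers), ","),
                                as.integer)]
  structure(list(planted_dmrs = reg[], coupled_genes = gen[], seed = seed),
            class = "truth_set")
}
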