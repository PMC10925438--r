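#' Build a queryable interval index from a feature catalog
#'
#' Wraps the catalog in a `GRanges` object (converted from the internal
#' 0-based half-open convention) for O(log n + k) overlap queries. Feature
#' strand is kept as metadata only, so queries are never strand-filtered.
#'
#' @param catalog a [feature_catalog()].
#' @return an object of class `interval_index`.
#' @export
build_interval_index <- function(catalog) {
  catalog <- feature_catalog(catalog)
  gr <- GenomicRanges::GRanges(
    seqnames = catalog$chrom,
    ranges = IRanges::IRanges(start = catalog$start + 1, end = catalog$end))
  S4Vectors::mcols(gr)$category <- catalog$category
  S4Vectors::mcols(gr)$gene_id <- catalog$gene_id
  S4Vectors::mcols(gr)$feature_strand <- catalog$strand
  structure(list(gr = gr, catalog = catalog), class = "interval_index")
}

#' @export
print.interval_index <- function(x, ...) {
  cat(sprintf("<interval_index> %d intervals\n", length(x$gr)))
  invisible(x)
}

#' Query an interval index
#'
#' Returns every catalog interval overlapping the half-open query by at least
#' 1 bp; abutting intervals (query end == feature start) do not overlap.
#'
#' @param index an `interval_index`.
#' @param chrom,start,end query interval (0-based half-open, vectorized).
#' @return data.table `query` (row of the query), `category`, `gene_id`,
#'   `overlap_bp`.
#' @export
query_overlaps <- function(index, chrom, start, end) {
  if (any(end <= start)) stopf("query_overlaps: query start must be < end")
  q <- GenomicRanges::GRanges(seqnames = chrom,
                              ranges = IRanges::IRanges(start = start + 1,
                                                        end = end))
  hits <- GenomicRanges::findOverlaps(q, index$gr, ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(data.table::data.table(query = integer(), category = character(),
                                  gene_id = character(), overlap_bp = integer()))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::pintersect(IRanges::ranges(q)[qi], IRanges::ranges(index$gr)[si])
  data.table::data.table(
    query = qi,
    category = index$catalog$category[si],
    gene_id = index$catalog$gene_id[si],
    overlap_bp = IRanges::width(ov))
}

#' Annotate DMRs with genomic elements
#'
#' Each DMR is matched against the interval index; it counts toward every
#' category it overlaps by at least 1 bp, but only once per category no
#' matter how many intervals of that category it touches (multi-hit,
#' intersect-style semantics). DMRs overlapping nothing are tallied as
#' unannotated.
#'
#' @param dmrs a DMR table (from [call_dmrs()] or [read_dmrs()]).
#' @param index an `interval_index` built on the same coordinate convention.
#' @return an object of class `annotated_dmrs`: list with `hits` (dmr row,
#'   category, gene_id, overlap_bp; one row per overlapped interval),
#'   `category_counts` (category x direction counts, once per DMR and
#'   category), `unannotated` (per-direction counts) and the input `dmrs`.
#' @export
annotate_dmrs <- function(dmrs, index) {
  dmrs <- data.table::as.data.table(dmrs)
  if (nrow(dmrs) == 0L) {
    return(structure(list(
      hits = data.table::data.table(dmr = integer(), category = character(),
                                    gene_id = character(), overlap_bp = integer()),
      category_counts = data.table::data.table(category = character(),
                                               direction = character(),
                                               n = integer()),
      unannotated = c(hypo = 0L, hyper = 0L),
      dmrs = dmrs), class = "annotated_dmrs"))
  }
  hits <- query_overlaps(index, dmrs$chrom, dmrs$start, dmrs$end)
  data.table::setnames(hits, "query", "dmr")
  percat <- unique(hits[, .(dmr, category)])
  percat[, direction := dmrs$direction[dmr]]
  counts <- percat[, .(n = .N), by = .(category, direction)]
  annotated <- unique(hits$dmr)
  unann <- setdiff(seq_len(nrow(dmrs)), annotated)
  unannotated <- c(hypo = sum(dmrs$direction[unann] == "hypo"),
                   hyper = sum(dmrs$direction[unann] == "hyper"))
  structure(list(hits = hits, category_counts = counts,
                 unannotated = unannotated, dmrs = dmrs),
            class = "annotated_dmrs")
}

#' @export
print.annotated_dmrs <- function(x, ...) {
  cat(sprintf("<annotated_dmrs> %d DMRs, %d feature hits\n",
              nrow(x$dmrs), nrow(x$hits)))
  if (nrow(x$category_counts)) print(x$category_counts)
  invisible(x)
}

#' Genomic-element distribution of a DMR signature
#'
#' Summarizes which genomic elements a set of regions (e.g. a core
#' methylation signature) falls in, under two schemes reported side by side:
#' multi-hit (a region counts in every category it overlaps, fractions may
#' exceed 1 in total) and exclusive priority (each region assigned to the
#' highest-priority category it overlaps, fractions sum to 1 including an
#' "unannotated" class).
#'
#' @param regions data.table with `chrom`, `start`, `end` (half-open).
#' @param index an `interval_index`.
#' @param priority category order for the exclusive scheme.
#' @return list with `multi` and `exclusive` data.tables of counts and
#'   fractions; both empty (with a warning) for an empty signature.
#' @export
signature_element_distribution <- function(regions, index,
                                           priority = c("promoter", "exon",
                                                        "intron", "enhancer",
                                                        "repeat")) {
  regions <- data.table::as.data.table(regions)
  if (nrow(regions) == 0L) {
    warnf("signature_element_distribution: empty signature")
    empty <- data.table::data.table(category = character(), n = integer(),
                                    fraction = numeric())
    return(list(multi = empty, exclusive = data.table::copy(empty)))
  }
  hits <- query_overlaps(index, regions$chrom, regions$start, regions$end)
  n_reg <- nrow(regions)

  multi <- unique(hits[, .(query, category)])[, .(n = .N), by = category]
  multi[, fraction := n / n_reg]

  assigned <- rep("unannotated", n_reg)
  for (cat_i in rev(priority)) {
    assigned[unique(hits[category == cat_i, query])] <- cat_i
  }
  excl <- data.table::data.table(category = assigned)[, .(n = .N), by = category]
  excl[, fraction := n / n_reg]
  lvls <- c(priority, "unannotated")
  data.table::setorder(excl[, ord := match(category, lvls)], ord)
  excl[, ord := NULL]
  list(multi = multi[], exclusive = excl[])
}
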