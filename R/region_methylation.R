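#' Weighted methylation level per region and context
#'
#' Computes, for every (gene, region kind, context) triple, the weighted
#' methylation level: the sum of methylated read calls divided by the sum of
#' all read calls over the covered cytosines inside the region.  Cytosines
#' on both DNA strands contribute, regardless of the gene's strand.  A
#' region/context with no covered cytosines gets an undefined (`NA`) level;
#' the triple is still reported.
#'
#' Records are expected to be coverage-filtered already (see
#' [filter_by_coverage()]); the level depends only on count sums, so it is
#' invariant to record order and additive over split inputs.
#'
#' @param records Cytosine records (coverage-filtered).
#' @param regions Region table from [derive_regions()]; duplicate
#'   (gene, kind) pairs are a configuration error.
#' @param contexts Contexts to report (default all three).
#' @return A `data.frame` with one row per (gene, kind, context):
#'   `gene_id`, `kind`, `context`, `level` (fraction in \[0,1\] or `NA`),
#'   `n_cytosines`, `meth_reads`, `total_reads`.
#' @export
profile_methylation <- function(records, regions,
                                contexts = METH_CONTEXTS) {
  stopifnot(is.data.frame(regions), all(contexts %in% METH_CONTEXTS))
  if (anyDuplicated(regions[, c("gene_id", "kind")]))
    stop("duplicate (gene_id, kind) region specifications")
  rec <- as.data.table(records)
  grid <- data.table::CJ(idx = seq_len(nrow(regions)),
                         context = contexts, sorted = FALSE)
  grid[, `:=`(gene_id = regions$gene_id[idx], kind = regions$kind[idx])]

  live <- regions[!regions$zero_length, , drop = FALSE]
  agg <- NULL
  if (nrow(live) && nrow(rec)) {
    gr_rec <- GenomicRanges::GRanges(rec$chrom,
                                     IRanges::IRanges(rec$pos, rec$pos))
    gr_reg <- regions_to_granges(live)
    hits <- GenomicRanges::findOverlaps(gr_rec, gr_reg, ignore.strand = TRUE)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits); sbj <- S4Vectors::subjectHits(hits)
      dt <- data.table(gene_id = live$gene_id[sbj], kind = live$kind[sbj],
                       context = rec$context[q],
                       m = rec$count_meth[q],
                       cov = rec$count_meth[q] + rec$count_unmeth[q])
      dt <- dt[context %in% contexts]
      agg <- dt[, .(meth_reads = sum(m), total_reads = sum(cov),
                    n_cytosines = sum(cov > 0L)),
                by = .(gene_id, kind, context)]
    }
  }
  if (is.null(agg))
    agg <- data.table(gene_id = character(), kind = character(),
                      context = character(), meth_reads = integer(),
                      total_reads = integer(), n_cytosines = integer())
  out <- merge(grid, agg, by = c("gene_id", "kind", "context"),
               all.x = TRUE, sort = FALSE)
  data.table::setorder(out, idx, context)
  for (col in c("meth_reads", "total_reads", "n_cytosines"))
    data.table::set(out, which(is.na(out[[col]])), col, 0L)
  out[, level := ifelse(total_reads > 0L, meth_reads / total_reads,
                        NA_real_)]
  out[, idx := NULL]
  data.table::setcolorder(out, c("gene_id", "kind", "context", "level",
                                 "n_cytosines", "meth_reads", "total_reads"))
  as.data.frame(out)
}

#' Weighted methylation level for one region
#'
#' @param records Coverage-filtered cytosine records.
#' @param region One-row region table (see [derive_regions()]).
#' @param context Context to summarise (`"CG"`, `"CHG"` or `"CHH"`).
#' @return One-row `data.frame` in the layout of [profile_methylation()].
#' @export
summarize_region <- function(records, region, context) {
  stopifnot(is.data.frame(region), nrow(region) == 1L,
            context %in% METH_CONTEXTS)
  profile_methylation(records, region, contexts = context)
}

#' Write / read a long-format methylation profile TSV
#'
#' Undefined levels are written as `NA`.
#'
#' @param profile Profile table from [profile_methylation()].
#' @param path File path.
#' @return `write_profile`: the path, invisibly; `read_profile`: the table.
#' @export
write_profile <- function(profile, path) {
  data.table::fwrite(profile, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}
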