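#' Load gene models from a GFF3 annotation
#'
#' Reads the `gene` feature lines of a GFF3 file and returns one gene model
#' per gene, with the transcription start and end sites (TSS/TES) assigned
#' from the feature's strand: on `+` the TSS is the feature start, on `-` it
#' is the feature end.  The gene feature line itself (not any mRNA isoform)
#' defines the model, so multi-isoform TSS selection never arises.
#'
#' @param gff_file Path to a GFF3 file.
#' @param gene_ids Optional character vector of gene identifiers; when given,
#'   only matching genes are returned (in file order).
#'
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `strand` (`"+"`/`"-"`), `tss`, `tes`.
#'
#' @details Malformed feature lines (not 9 tab-separated fields) raise an
#'   error naming the offending line number.  Genes without a strand are
#'   dropped with a warning, since no upstream window can be oriented for
#'   them.
#'
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "Chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=g1"), gff)
#' read_gene_models(gff)
#' @export
read_gene_models <- function(gff_file, gene_ids = NULL) {
  stopifnot(is.character(gff_file), length(gff_file) == 1L, file.exists(gff_file))
  lines <- readLines(gff_file)
  data_ln <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(data_ln)) {
    nf <- lengths(strsplit(lines[data_ln], "\t", fixed = TRUE))
    bad <- which(nf != 9L)
    if (length(bad)) {
      stop(sprintf(
        "malformed GFF3 line %d: expected 9 tab-separated fields, found %d",
        data_ln[bad[1L]], nf[bad[1L]]))
    }
  }
  gr <- rtracklayer::import(gff_file, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "gene"]
  if (length(gr) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), tss = integer(), tes = integer(),
                      stringsAsFactors = FALSE))
  }
  ids <- as.character(gr$ID)
  if (anyNA(ids)) stop("gene feature without an ID attribute")
  str <- as.character(GenomicRanges::strand(gr))
  no_strand <- str == "*"
  if (any(no_strand)) {
    warning(sprintf("%d gene(s) without strand rejected: %s",
                    sum(no_strand),
                    paste(head(ids[no_strand], 5L), collapse = ", ")))
    gr <- gr[!no_strand]; ids <- ids[!no_strand]; str <- str[!no_strand]
  }
  models <- data.frame(
    gene_id = ids,
    chrom   = as.character(GenomicRanges::seqnames(gr)),
    start   = GenomicRanges::start(gr),
    end     = GenomicRanges::end(gr),
    strand  = str,
    stringsAsFactors = FALSE)
  models$tss <- ifelse(models$strand == "+", models$start, models$end)
  models$tes <- ifelse(models$strand == "+", models$end, models$start)
  if (!is.null(gene_ids)) models <- models[models$gene_id %in% gene_ids, ]
  rownames(models) <- NULL
  models
}

#' Derive analysis windows (UPR200, UPR500, GBR) for gene models
#'
#' For each gene three windows are produced: the gene body region (GBR,
#' the full gene span from TSS to TES) and the 200-bp and 500-bp upstream
#' regions (UPRs) lying immediately 5' of the TSS on the gene's strand.
#' On `+` the L-bp UPR is `[max(1, tss - L), tss - 1]`; on `-` it is
#' `[tss + 1, min(chrom_length, tss + L)]`.  Windows are clipped at the
#' chromosome ends; a window clipped to nothing (TSS at the sequence edge)
#' is emitted with `zero_length = TRUE` and `NA` coordinates, and is
#' excluded from overlap-based summaries downstream.
#'
#' UPR windows are not trimmed when they run into a neighbouring gene.
#'
#' @param genes Gene models as returned by [read_gene_models()].
#' @param chrom_lengths Named integer vector of chromosome lengths covering
#'   every chromosome in `genes`.
#'
#' @return A `data.frame` with columns `gene_id`, `kind`
#'   (`"UPR200"`/`"UPR500"`/`"GBR"`), `chrom`, `start`, `end` (1-based
#'   inclusive), `strand`, `zero_length`; three rows per gene.
#' @export
derive_regions <- function(genes, chrom_lengths) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "start", "end", "strand", "tss")
                %in% names(genes)))
  if (nrow(genes) == 0L) {
    return(data.frame(gene_id = character(), kind = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), zero_length = logical(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(chrom_lengths)) ||
      !all(genes$chrom %in% names(chrom_lengths)))
    stop("chrom_lengths must be a named vector covering every chromosome")
  clen <- as.integer(chrom_lengths[genes$chrom])
  if (any(genes$end > clen))
    stop("gene end exceeds chromosome length (coordinate error)")

  one_kind <- function(kind, L) {
    if (kind == "GBR") {
      s <- genes$start; e <- genes$end
    } else {
      plus <- genes$strand == "+"
      s <- ifelse(plus, pmax(1L, genes$tss - L), genes$tss + 1L)
      e <- ifelse(plus, genes$tss - 1L, pmin(clen, genes$tss + L))
    }
    zero <- s > e
    data.frame(gene_id = genes$gene_id, kind = kind, chrom = genes$chrom,
               start = ifelse(zero, NA_integer_, as.integer(s)),
               end   = ifelse(zero, NA_integer_, as.integer(e)),
               strand = genes$strand, zero_length = zero,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_kind("UPR200", 200L), one_kind("UPR500", 500L),
               one_kind("GBR", 0L))
  out <- out[order(match(out$gene_id, genes$gene_id),
                   match(out$kind, REGION_KINDS)), ]
  rownames(out) <- NULL
  out
}

#' Convert a region table to a GRanges object
#'
#' Zero-length (clipped-away) windows are dropped.
#'
#' @param regions Region table from [derive_regions()].
#' @return A [GenomicRanges::GRanges] with `gene_id` and `kind` metadata.
#' @export
regions_to_granges <- function(regions) {
  r <- regions[!regions$zero_length, , drop = FALSE]
  GenomicRanges::GRanges(
    seqnames = r$chrom,
    ranges   = IRanges::IRanges(start = r$start, end = r$end),
    strand   = r$strand,
    gene_id  = r$gene_id,
    kind     = r$kind)
}

#' Export derived regions as BED6
#'
#' Coordinates are converted to BED's 0-based half-open convention at the
#' boundary (handled by rtracklayer).  The name field is `gene_id|kind`.
#'
#' @param regions Region table from [derive_regions()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_regions_bed <- function(regions, path) {
  gr <- regions_to_granges(regions)
  names(gr) <- paste(gr$gene_id, gr$kind, sep = "|")
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
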