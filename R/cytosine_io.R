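#' Read a per-cytosine methylation call report
#'
#' Parses the 7-column tab-delimited per-cytosine report layout written by
#' bisulfite methylation extractors (Bismark cytosine/CX report): chromosome,
#' 1-based position, strand, methylated read count, unmethylated read count,
#' context (`CG`/`CHG`/`CHH`), trinucleotide.  Gzip-compressed files are
#' handled transparently.  Rows with zero coverage are kept; they are removed
#' later by [filter_by_coverage()] and never contribute to levels.
#'
#' @param path Path to the report (optionally `.gz`).
#' @return A `data.table` with columns `chrom`, `pos`, `strand`,
#'   `count_meth`, `count_unmeth`, `context`, `trinucleotide`.
#' @export
read_cytosine_report <- function(path) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, header = FALSE, sep = "\t", quote = "",
                          colClasses = "character")
  if (ncol(dt) != 7L)
    stop(sprintf("cytosine report must have 7 tab-separated columns, found %d",
                 ncol(dt)))
  data.table::setnames(dt, c("chrom", "pos", "strand", "count_meth",
                             "count_unmeth", "context", "trinucleotide"))
  .first_bad <- function(ok, what) {
    if (!all(ok))
      stop(sprintf("cytosine report line %d: %s", which(!ok)[1L], what))
  }
  is_int <- function(x) grepl("^[0-9]+$", x)
  .first_bad(is_int(dt$pos), "position is not a non-negative integer")
  .first_bad(is_int(dt$count_meth) & is_int(dt$count_unmeth),
             "read counts are not non-negative integers")
  .first_bad(dt$strand %in% c("+", "-"), "strand must be '+' or '-'")
  .first_bad(dt$context %in% METH_CONTEXTS,
             "context must be one of CG, CHG, CHH")
  dt[, `:=`(pos = as.integer(pos),
            count_meth = as.integer(count_meth),
            count_unmeth = as.integer(count_unmeth))]
  dt[]
}

#' Write a per-cytosine report (7-column TSV, no header)
#'
#' @param records Cytosine records as from [read_cytosine_report()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cytosine_report <- function(records, path) {
  cols <- c("chrom", "pos", "strand", "count_meth", "count_unmeth",
            "context", "trinucleotide")
  data.table::fwrite(as.data.table(records)[, cols, with = FALSE], path,
                     sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter cytosines by read coverage
#'
#' Keeps cytosines whose total read count (methylated + unmethylated) is at
#' least `min_cov`; the default of 4 reads follows common practice for
#' retaining dependable sequencing sites.  Coverage is counted per
#' strand-specific cytosine; strands are never pooled at symmetric CG dyads.
#' Input order is preserved, and the filter is idempotent.
#'
#' @param records Cytosine records.
#' @param min_cov Minimum total reads (>= 1); a record with exactly
#'   `min_cov` reads is kept.
#' @return The retained records.
#' @export
filter_by_coverage <- function(records, min_cov = 4L) {
  stopifnot(is.numeric(min_cov), length(min_cov) == 1L, min_cov >= 1)
  dt <- as.data.table(records)
  dt[count_meth + count_unmeth >= min_cov][]
}

.complement <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

.context_from_bases <- function(b2, b3) {
  # b2/b3 are the two bases 3' of the cytosine on its own strand;
  # NA means truncated by the sequence end.  The minimal determining
  # window is used: CG needs only b2, CHG/CHH need b3 as well.
  ctx <- rep(NA_character_, length(b2))
  known2 <- !is.na(b2) & b2 %in% c("A", "C", "G", "T")
  ctx[known2 & b2 == "G"] <- "CG"
  needs3 <- known2 & b2 != "G"
  known3 <- needs3 & !is.na(b3) & b3 %in% c("A", "C", "G", "T")
  ctx[known3 & b3 == "G"] <- "CHG"
  ctx[known3 & b3 != "G"] <- "CHH"
  ctx
}

#' Call the methylation sequence context at genomic positions
#'
#' For a `+` strand position the reference base must be `C` and the context
#' is read from the next one or two reference bases (`CG` if the next base is
#' `G`, `CHG` for C-H-G, otherwise `CHH`, with H being A, C or T).  For a `-`
#' strand position the reference base must be `G` and the context is read
#' from the complemented bases at `pos - 1` and `pos - 2`.  A position whose
#' reference base is not a cytosine on the requested strand, or whose
#' determining window is truncated by the sequence end or contains `N`,
#' yields `NA` (not a cytosine / undeterminable) rather than defaulting to
#' CHH.
#'
#' @param genome A [Biostrings::DNAStringSet] (uppercase) or path to a FASTA
#'   file.
#' @param chrom Chromosome name (scalar, or vector parallel to `pos`).
#' @param pos 1-based positions.
#' @param strand `"+"`/`"-"`, recycled to `length(pos)`.
#' @return Character vector over `{"CG","CHG","CHH", NA}`.
#' @export
call_context <- function(genome, chrom, pos, strand) {
  genome <- .as_genome(genome)
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  stopifnot(all(strand %in% c("+", "-")))
  out <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    if (!ch %in% names(genome)) stop(sprintf("unknown chromosome '%s'", ch))
    s <- .chrom_chars(genome, ch)
    len <- length(s)
    i <- which(chrom == ch)
    p <- pos[i]
    if (any(p < 1L | p > len))
      stop(sprintf("position out of range for chromosome '%s'", ch))
    at <- function(q) ifelse(q >= 1L & q <= len, s[pmax(pmin(q, len), 1L)],
                             NA_character_)
    plus <- strand[i] == "+"
    ip <- i[plus]; pp <- p[plus]
    if (length(ip)) {
      isC <- s[pp] == "C"
      ctx <- .context_from_bases(at(pp + 1L), at(pp + 2L))
      out[ip] <- ifelse(isC, ctx, NA_character_)
    }
    im <- i[!plus]; pm <- p[!plus]
    if (length(im)) {
      isC <- s[pm] == "G"
      ctx <- .context_from_bases(.complement(at(pm - 1L)),
                                 .complement(at(pm - 2L)))
      out[im] <- ifelse(isC, ctx, NA_character_)
    }
  }
  out
}

.as_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (is.null(names(genome))) stop("genome sequences must be named")
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

.chrom_chars <- function(genome, ch) {
  strsplit(toupper(as.character(genome[[ch]])), "", fixed = TRUE)[[1L]]
}

#' Enumerate every cytosine position in a genome
#'
#' Lists all `C` positions on the `+` strand and all `G` positions (i.e.
#' minus-strand cytosines) with their called context and read-strand
#' trinucleotide.  Positions with an undeterminable context (sequence edge
#' or `N` in the window) are excluded.
#'
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @return A `data.table` with columns `chrom`, `pos`, `strand`, `context`,
#'   `trinucleotide`, sorted by chromosome and position.
#' @export
enumerate_cytosines <- function(genome) {
  genome <- .as_genome(genome)
  res <- vector("list", length(genome))
  for (k in seq_along(genome)) {
    ch <- names(genome)[k]
    s <- .chrom_chars(genome, ch)
    len <- length(s)
    at <- function(q) ifelse(q >= 1L & q <= len, s[pmax(pmin(q, len), 1L)],
                             NA_character_)
    pad <- function(x) ifelse(is.na(x), "N", x)
    pp <- which(s == "C")
    pctx <- .context_from_bases(at(pp + 1L), at(pp + 2L))
    ptri <- paste0("C", pad(at(pp + 1L)), pad(at(pp + 2L)))
    pm <- which(s == "G")
    b2 <- .complement(at(pm - 1L)); b3 <- .complement(at(pm - 2L))
    mctx <- .context_from_bases(b2, b3)
    mtri <- paste0("C", pad(b2), pad(b3))
    dt <- data.table(
      chrom = ch,
      pos = c(pp, pm),
      strand = rep(c("+", "-"), c(length(pp), length(pm))),
      context = c(pctx, mctx),
      trinucleotide = c(ptri, mtri))
    res[[k]] <- dt[!is.na(context)]
  }
  out <- data.table::rbindlist(res)
  data.table::setorder(out, chrom, pos, strand)
  out[]
}
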