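# Shared fixture builders and independent oracles used across test files.

# Write a small GFF3 file from parallel vectors; returns the path.
write_test_gff <- function(chrom, start, end, strand, id,
                           path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3",
               sprintf("%s\tsrc\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       chrom, start, end, strand, id)),
             path)
  path
}

# Cytosine record table from parallel vectors.
make_records <- function(pos, m, u, context = "CG", chrom = "Chr1",
                         strand = "+") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             count_meth = as.integer(m), count_unmeth = as.integer(u),
             context = context, trinucleotide = "CGN",
             stringsAsFactors = FALSE)
}

# One-row region table.
make_region <- function(start, end, gene_id = "g1", kind = "GBR",
                        chrom = "Chr1", strand = "+") {
  data.frame(gene_id = gene_id, kind = kind, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             strand = strand, zero_length = FALSE, stringsAsFactors = FALSE)
}

# Independent brute-force weighted-level oracle: plain loop over records,
# no pooling shortcuts shared with the implementation.
brute_force_level <- function(records, start, end, context) {
  m <- 0; tot <- 0; n <- 0
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$pos >= start && r$pos <= end && r$context == context) {
      cov <- r$count_meth + r$count_unmeth
      if (cov > 0) {
        m <- m + r$count_meth
        tot <- tot + cov
        n <- n + 1
      }
    }
  }
  list(level = if (tot > 0) m / tot else NA_real_, n_cytosines = n,
       meth_reads = m, total_reads = tot)
}

# Independent plus-strand context caller used as oracle for call_context:
# works on a character sequence, minimal determining window.
oracle_context_plus <- function(seq_chars, p) {
  len <- length(seq_chars)
  if (seq_chars[p] != "C") return(NA_character_)
  b2 <- if (p + 1 <= len) seq_chars[p + 1] else NA_character_
  if (is.na(b2) || !b2 %in% c("A", "C", "G", "T")) return(NA_character_)
  if (b2 == "G") return("CG")
  b3 <- if (p + 2 <= len) seq_chars[p + 2] else NA_character_
  if (is.na(b3) || !b3 %in% c("A", "C", "G", "T")) return(NA_character_)
  if (b3 == "G") "CHG" else "CHH"
}

revcomp_chars <- function(x) rev(chartr("ACGT", "TGCA", x))
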