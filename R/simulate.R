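#' Simulation configuration for a synthetic methylome/expression study
#'
#' Bundles and validates all generator parameters.  The defaults describe a
#' desk-scale stand-in for a two-genotype (wild type vs demethylase mutant)
#' bisulfite + mRNA-Seq study of a 144-gene resistance-gene panel: two 250-kb
#' chromosomes at Arabidopsis-like 36% GC, genes of 1.5-3 kb placed with at
#' least 600 bp spacing (so 500-bp upstream windows never touch a
#' neighbour), mean read coverage 50 per cytosine, and context baselines of
#' 0.24/0.10/0.03 for CG/CHG/CHH.  Within-region heterogeneity follows a
#' beta-binomial with concentration `dispersion_kappa`; `Inf` recovers the
#' pure binomial used in closed-form checks.
#'
#' @param seed Integer master seed (< 2^31 - 16); every generator derives
#'   its stream from it.
#' @param n_chromosomes,chrom_length_bp Genome shape.
#' @param n_genes Number of genes (all listed in the simulated NLR panel).
#' @param gene_length_range Min/max gene length in bp.
#' @param fraction_minus_strand Probability a gene lies on `-`.
#' @param gc_fraction Genome GC content in \[0, 1\].
#' @param coverage_lambda Mean (Poisson) reads per cytosine.
#' @param baseline_levels Named per-context true methylation fractions.
#' @param dispersion_kappa Beta-binomial concentration (> 0 or `Inf`).
#' @param planted_dm `NULL` or a `data.frame` with `gene_id`, `kind`,
#'   `context`, `delta_pp`: mutant-minus-wild-type true-level shifts in
#'   percentage points, clamped so levels stay in \[0, 1\].
#' @param planted_expr `NULL` or a `data.frame` with `gene_id`, `ratio`:
#'   planted mutant/wild-type expression ratios.
#' @param expr_noise_sigma Lognormal sdlog of multiplicative FPKM noise.
#' @param fpkm_meanlog,fpkm_sdlog Lognormal baseline FPKM parameters.
#' @param min_gene_gap_bp Minimum spacing between genes (and from the
#'   chromosome start), in bp.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length_bp = 250000L,
                       n_genes = 144L,
                       gene_length_range = c(1500L, 3000L),
                       fraction_minus_strand = 0.5,
                       gc_fraction = 0.36,
                       coverage_lambda = 50,
                       baseline_levels = c(CG = 0.24, CHG = 0.10,
                                           CHH = 0.03),
                       dispersion_kappa = 20,
                       planted_dm = NULL,
                       planted_expr = NULL,
                       expr_noise_sigma = 0.05,
                       fpkm_meanlog = log(10),
                       fpkm_sdlog = 0.8,
                       min_gene_gap_bp = 600L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed == floor(seed),
            seed >= 0, seed < 2^31 - 16,
            n_chromosomes >= 1L, chrom_length_bp >= 1000L, n_genes >= 1L,
            length(gene_length_range) == 2L,
            gene_length_range[1] >= 1L,
            gene_length_range[1] <= gene_length_range[2],
            fraction_minus_strand >= 0, fraction_minus_strand <= 1,
            gc_fraction >= 0, gc_fraction <= 1,
            coverage_lambda > 0,
            all(METH_CONTEXTS %in% names(baseline_levels)),
            all(baseline_levels >= 0 & baseline_levels <= 1),
            dispersion_kappa > 0,
            expr_noise_sigma >= 0, fpkm_sdlog >= 0, min_gene_gap_bp >= 1L)
  if (!is.null(planted_dm)) {
    stopifnot(is.data.frame(planted_dm),
              all(c("gene_id", "kind", "context", "delta_pp")
                  %in% names(planted_dm)),
              all(planted_dm$kind %in% REGION_KINDS),
              all(planted_dm$context %in% METH_CONTEXTS))
  }
  if (!is.null(planted_expr)) {
    stopifnot(is.data.frame(planted_expr),
              all(c("gene_id", "ratio") %in% names(planted_expr)),
              all(planted_expr$ratio > 0))
  }
  structure(list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.integer(chrom_length_bp),
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    fraction_minus_strand = fraction_minus_strand,
    gc_fraction = gc_fraction, coverage_lambda = coverage_lambda,
    baseline_levels = baseline_levels[METH_CONTEXTS],
    dispersion_kappa = dispersion_kappa,
    planted_dm = planted_dm, planted_expr = planted_expr,
    expr_noise_sigma = expr_noise_sigma,
    fpkm_meanlog = fpkm_meanlog, fpkm_sdlog = fpkm_sdlog,
    min_gene_gap_bp = as.integer(min_gene_gap_bp)),
    class = "sim_config")
}

.sim_seed <- function(config, offset) set.seed(config$seed + offset)

#' Simulate a random genome
#'
#' Uppercase i.i.d. sequence at the configured GC fraction; deterministic
#' given the configuration seed.
#'
#' @param config A [sim_config()].
#' @return A named [Biostrings::DNAStringSet] (`Chr1`, `Chr2`, ...).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .sim_seed(config, 0L)
  p <- c(A = (1 - config$gc_fraction) / 2, C = config$gc_fraction / 2,
         G = config$gc_fraction / 2, T = (1 - config$gc_fraction) / 2)
  seqs <- vapply(seq_len(config$n_chromosomes), function(i) {
    paste(sample(names(p), config$chrom_length_bp, replace = TRUE,
                 prob = p), collapse = "")
  }, "")
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("Chr", seq_len(config$n_chromosomes))
  genome
}

#' Simulate a gene annotation over a genome
#'
#' Places non-overlapping genes with at least `min_gene_gap_bp` spacing
#' (also kept from the chromosome start, so all 500-bp upstream windows are
#' clean), random lengths and strands.  Every simulated gene is listed in
#' the returned NLR panel.
#'
#' @param config A [sim_config()].
#' @param genome Genome from [simulate_genome()].
#' @return A list: `genes` (gene-model `data.frame` as from
#'   [read_gene_models()]) and `nlr_ids` (character vector).
#' @export
simulate_annotation <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  .sim_seed(config, 1L)
  n <- config$n_genes
  gap <- config$min_gene_gap_bp
  lens <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                 n, replace = TRUE)
  chrom_of <- rep(seq_len(config$n_chromosomes), length.out = n)
  clen <- config$chrom_length_bp
  starts <- integer(n); chroms <- character(n)
  for (ci in seq_len(config$n_chromosomes)) {
    idx <- which(chrom_of == ci)
    k <- length(idx)
    if (k == 0L) next
    need <- sum(lens[idx]) + (k + 1L) * gap
    if (need > clen)
      stop("infeasible gene packing: reduce n_genes or gene lengths, ",
           "or enlarge chromosomes")
    slack <- clen - need
    w <- runif(k + 1L)
    extra <- floor(slack * cumsum(w) / sum(w))
    extra <- diff(c(0, extra))
    s <- gap + extra[1L] + 1L
    for (j in seq_len(k)) {
      starts[idx[j]] <- s
      s <- s + lens[idx[j]] - 1L + gap + extra[j + 1L] + 1L
    }
    chroms[idx] <- paste0("Chr", ci)
  }
  strand <- ifelse(runif(n) < config$fraction_minus_strand, "-", "+")
  genes <- data.frame(
    gene_id = sprintf("SIMG%04d", seq_len(n)),
    chrom = chroms, start = starts, end = starts + lens - 1L,
    strand = strand, stringsAsFactors = FALSE)
  genes$tss <- ifelse(strand == "+", genes$start, genes$end)
  genes$tes <- ifelse(strand == "+", genes$end, genes$start)
  list(genes = genes, nlr_ids = genes$gene_id)
}

.true_levels <- function(config, cyt, regions) {
  # Per-cytosine true methylation fractions for both genotypes: the
  # context baseline everywhere, plus the planted percentage-point shifts
  # (accumulated when planted windows overlap) clamped to [0, 1] in the
  # mutant.
  base <- config$baseline_levels[cyt$context]
  p_wt <- unname(base)
  p_mut <- p_wt
  pd <- config$planted_dm
  if (!is.null(pd) && nrow(pd)) {
    key <- paste(regions$gene_id, regions$kind)
    for (i in seq_len(nrow(pd))) {
      r <- regions[match(paste(pd$gene_id[i], pd$kind[i]), key), ]
      if (is.na(r$gene_id))
        stop(sprintf("planted_dm names unknown region %s/%s",
                     pd$gene_id[i], pd$kind[i]))
      if (r$zero_length) next
      hit <- cyt$chrom == r$chrom & cyt$pos >= r$start & cyt$pos <= r$end &
        cyt$context == pd$context[i]
      p_mut[hit] <- p_mut[hit] + pd$delta_pp[i] / 100
    }
    p_mut <- pmin(pmax(p_mut, 0), 1)
  }
  list(wt = p_wt, mut = p_mut)
}

.sample_counts <- function(p, lambda, kappa) {
  n <- length(p)
  cov <- rpois(n, lambda)
  if (is.finite(kappa)) {
    pc <- p
    mid <- p > 0 & p < 1
    pc[mid] <- rbeta(sum(mid), p[mid] * kappa, (1 - p[mid]) * kappa)
  } else {
    pc <- p
  }
  meth <- rbinom(n, cov, pc)
  data.table(count_meth = meth, count_unmeth = cov - meth)
}

#' Simulate two-genotype per-cytosine methylation reports
#'
#' Every cytosine in the genome (both strands) is emitted, including
#' zero-coverage positions, in the 7-column per-cytosine report layout.
#' Coverage is Poisson(`coverage_lambda`); the per-cytosine methylation
#' probability is drawn Beta(p kappa, (1-p) kappa) around the region's true
#' level p and reads are binomial.  Wild type uses the context baselines;
#' the mutant adds the planted shifts.  The returned truth table records,
#' per (gene, kind, context), the mean true per-cytosine level in each
#' genotype.
#'
#' @param config A [sim_config()].
#' @param genome Genome from [simulate_genome()].
#' @param genes Gene models from [simulate_annotation()].
#' @return A list: `wt` and `mut` cytosine-record `data.table`s, and
#'   `truth` (`gene_id`, `kind`, `context`, `true_level_wt`,
#'   `true_level_mut`, `n_cytosines`, `planted`).
#' @export
simulate_methylomes <- function(config, genome, genes) {
  stopifnot(inherits(config, "sim_config"))
  cyt <- enumerate_cytosines(genome)
  chrom_lengths <- stats::setNames(Biostrings::width(genome), names(genome))
  regions <- derive_regions(genes, chrom_lengths)
  p <- .true_levels(config, cyt, regions)

  .sim_seed(config, 2L)
  wt_counts <- .sample_counts(p$wt, config$coverage_lambda,
                              config$dispersion_kappa)
  mut_counts <- .sample_counts(p$mut, config$coverage_lambda,
                               config$dispersion_kappa)
  report <- function(counts) {
    dt <- data.table(chrom = cyt$chrom, pos = cyt$pos, strand = cyt$strand,
                     count_meth = counts$count_meth,
                     count_unmeth = counts$count_unmeth,
                     context = cyt$context,
                     trinucleotide = cyt$trinucleotide)
    dt
  }

  live <- regions[!regions$zero_length, , drop = FALSE]
  gr_c <- GenomicRanges::GRanges(cyt$chrom, IRanges::IRanges(cyt$pos, cyt$pos))
  gr_r <- regions_to_granges(live)
  hits <- GenomicRanges::findOverlaps(gr_c, gr_r, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); sbj <- S4Vectors::subjectHits(hits)
  tt <- data.table(gene_id = live$gene_id[sbj], kind = live$kind[sbj],
                   context = cyt$context[q],
                   p_wt = p$wt[q], p_mut = p$mut[q])
  truth <- tt[, .(true_level_wt = mean(p_wt), true_level_mut = mean(p_mut),
                  n_cytosines = .N),
              by = .(gene_id, kind, context)]
  grid <- data.table::CJ(gene_id = genes$gene_id, kind = REGION_KINDS,
                         context = METH_CONTEXTS, sorted = FALSE)
  truth <- merge(grid, truth, by = c("gene_id", "kind", "context"),
                 all.x = TRUE, sort = FALSE)
  truth[is.na(n_cytosines), n_cytosines := 0L]
  pd <- config$planted_dm
  truth[, planted := if (is.null(pd)) FALSE else
    paste(gene_id, kind, context) %in%
      paste(pd$gene_id, pd$kind, pd$context)]
  data.table::setorder(truth, gene_id, kind, context)

  list(wt = report(wt_counts), mut = report(mut_counts),
       truth = as.data.frame(truth))
}

#' Simulate two-genotype FPKM tables with planted ratios
#'
#' Wild-type FPKMs are lognormal; mutant FPKMs are the wild-type value times
#' the planted ratio (1 when unplanted) times multiplicative lognormal noise
#' with sdlog `expr_noise_sigma`.
#'
#' @param config A [sim_config()].
#' @param gene_ids Gene identifiers to simulate.
#' @return A list: `expr` (`gene_id`, `fpkm_wt`, `fpkm_mut`) and `truth`
#'   (`gene_id`, `true_ratio`).
#' @export
simulate_expression <- function(config, gene_ids) {
  stopifnot(inherits(config, "sim_config"), length(gene_ids) >= 1L)
  .sim_seed(config, 3L)
  n <- length(gene_ids)
  ratio <- rep(1, n)
  pe <- config$planted_expr
  if (!is.null(pe) && nrow(pe)) {
    i <- match(pe$gene_id, gene_ids)
    if (anyNA(i)) stop("planted_expr names unknown gene IDs")
    ratio[i] <- pe$ratio
  }
  fpkm_wt <- rlnorm(n, config$fpkm_meanlog, config$fpkm_sdlog)
  noise <- if (config$expr_noise_sigma > 0)
    rlnorm(n, 0, config$expr_noise_sigma) else rep(1, n)
  expr <- data.frame(gene_id = gene_ids, fpkm_wt = fpkm_wt,
                     fpkm_mut = fpkm_wt * ratio * noise,
                     stringsAsFactors = FALSE)
  list(expr = expr,
       truth = data.frame(gene_id = gene_ids, true_ratio = ratio,
                          stringsAsFactors = FALSE))
}

#' Simulate a long-format qPCR Ct table
#'
#' Ct values are built so that the expected 2^-ddCt fold change of each
#' transcript equals its entry in `fold_changes`; the reference assay sits
#' at a fixed Ct in both conditions and replicate noise is Gaussian.
#'
#' @param config A [sim_config()] (supplies the seed).
#' @param fold_changes Named numeric vector: transcript ID -> true fold
#'   change.
#' @param n_replicates Technical replicates per assay (default 3).
#' @param ct_target_base,ct_ref Baseline target / reference Ct (cycles).
#' @param noise_sd Replicate noise sd in cycles (0 gives exact folds).
#' @return A long `data.frame` (`transcript_id`, `condition`, `role`,
#'   `replicate`, `ct`) with conditions `"control"` and `"test"`.
#' @export
simulate_ct <- function(config, fold_changes, n_replicates = 3L,
                        ct_target_base = 24, ct_ref = 18, noise_sd = 0.1) {
  stopifnot(inherits(config, "sim_config"), !is.null(names(fold_changes)),
            all(fold_changes > 0), n_replicates >= 1L, noise_sd >= 0)
  .sim_seed(config, 4L)
  rows <- list()
  for (id in names(fold_changes)) {
    mk <- function(condition, role, mu) {
      data.frame(transcript_id = id, condition = condition, role = role,
                 replicate = seq_len(n_replicates),
                 ct = mu + rnorm(n_replicates, 0, noise_sd),
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- rbind(
      mk("control", "target", ct_target_base),
      mk("control", "reference", ct_ref),
      mk("test", "target", ct_target_base - log2(fold_changes[[id]])),
      mk("test", "reference", ct_ref))
  }
  do.call(rbind, rows)
}

#' Write a gene annotation as GFF3
#'
#' @param genes Gene-model table.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_annotation_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tregmeth_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start, genes$end, genes$strand,
                     genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full synthetic study and write all artefacts
#'
#' Generates genome, annotation, two-genotype cytosine reports, FPKM table,
#' Ct table and truth tables, writing plain-text files (FASTA, GFF3, gene
#' list, 7-column report TSVs, TSV/CSV tables) under `dir`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects and file `paths`.
#' @export
simulate_study <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  genome <- simulate_genome(config)
  ann <- simulate_annotation(config, genome)
  meth <- simulate_methylomes(config, genome, ann$genes)
  expr <- simulate_expression(config, ann$genes$gene_id)
  folds <- c(example_half = 0.5, example_equal = 1, example_quadruple = 4)
  ct <- simulate_ct(config, folds, noise_sd = 0)

  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "annotation.gff3"),
    gene_list = file.path(dir, "nlr_genes.txt"),
    report_wt = file.path(dir, "cytosine_report_wt.tsv"),
    report_mut = file.path(dir, "cytosine_report_mut.tsv"),
    fpkm = file.path(dir, "fpkm.tsv"),
    ct = file.path(dir, "ct.csv"),
    truth_meth = file.path(dir, "truth_methylation.tsv"),
    truth_expr = file.path(dir, "truth_expression.tsv"))
  Biostrings::writeXStringSet(genome, paths$genome)
  write_annotation_gff3(ann$genes, paths$gff3)
  writeLines(ann$nlr_ids, paths$gene_list)
  write_cytosine_report(meth$wt, paths$report_wt)
  write_cytosine_report(meth$mut, paths$report_mut)
  data.table::fwrite(expr$expr, paths$fpkm, sep = "\t", quote = FALSE)
  data.table::fwrite(ct, paths$ct, quote = FALSE)
  data.table::fwrite(meth$truth, paths$truth_meth, sep = "\t", na = "NA",
                     quote = FALSE)
  data.table::fwrite(expr$truth, paths$truth_expr, sep = "\t", quote = FALSE)

  invisible(list(config = config, genome = genome, genes = ann$genes,
                 nlr_ids = ann$nlr_ids, methylomes = meth,
                 expression = expr, ct = ct, paths = paths))
}
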