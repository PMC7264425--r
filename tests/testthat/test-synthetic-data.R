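# Reduced-size configuration used throughout: determinism and structural
# properties do not depend on the full study scale.
small_cfg <- function(seed = 11, n_genes = 12L, chrom_length_bp = 30000L,
                      ...) {
  sim_config(seed = seed, n_chromosomes = 2L,
             chrom_length_bp = chrom_length_bp, n_genes = n_genes,
             gene_length_range = c(800L, 1500L), ...)
}

test_that("genome simulation is deterministic and honours GC settings", {
  cfg <- small_cfg()
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1), as.character(g2))
  expect_equal(length(g1), 2L)
  expect_equal(unname(Biostrings::width(g1)), rep(30000L, 2))
  at_only <- simulate_genome(small_cfg(gc_fraction = 0))
  counts <- Biostrings::alphabetFrequency(at_only[[1]], baseOnly = TRUE)
  expect_equal(sum(counts[c("C", "G")]), 0L)
  gc <- Biostrings::alphabetFrequency(g1[[1]], baseOnly = TRUE)
  expect_equal(sum(gc[c("C", "G")]) / 30000, 0.36, tolerance = 0.05)
})

test_that("annotation places spaced genes and lists the full panel", {
  cfg <- small_cfg()
  genome <- simulate_genome(cfg)
  ann <- simulate_annotation(cfg, genome)
  expect_equal(nrow(ann$genes), 12L)
  expect_equal(ann$nlr_ids, ann$genes$gene_id)
  expect_true(all(ann$genes$end <= 30000L))
  for (ch in unique(ann$genes$chrom)) {
    g <- ann$genes[ann$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start >= 601L))          # room for a clean UPR500 + gap
    if (nrow(g) > 1)
      expect_true(all(g$start[-1] - g$end[-nrow(g)] - 1L >= 600L))
  }
  all_plus <- simulate_annotation(small_cfg(fraction_minus_strand = 0),
                                  genome)
  expect_true(all(all_plus$genes$strand == "+"))
  expect_error(
    simulate_annotation(sim_config(seed = 1, chrom_length_bp = 5000L,
                                   n_genes = 50L), genome),
    "infeasible")
})

test_that("same seed gives byte-identical study artefacts", {
  cfg <- small_cfg(seed = 23)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  simulate_study(cfg, d1)
  simulate_study(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6),
                     label = paste("bytes of", f))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("methylome reports keep zero-coverage cytosines and honour truth", {
  cfg <- small_cfg(seed = 31, coverage_lambda = 5)
  genome <- simulate_genome(cfg)
  ann <- simulate_annotation(cfg, genome)
  sim <- simulate_methylomes(cfg, genome, ann$genes)
  expect_true(any(sim$wt$count_meth + sim$wt$count_unmeth == 0))
  # reports list every context-determinable cytosine of the genome
  expect_equal(nrow(sim$wt), nrow(enumerate_cytosines(genome)))
  # contexts in the report match a direct call on the genome
  idx <- sample(nrow(sim$wt), 200)
  expect_equal(sim$wt$context[idx],
               call_context(genome, sim$wt$chrom[idx], sim$wt$pos[idx],
                            sim$wt$strand[idx]))
})

test_that("planted shifts appear in the truth table and clamp to [0, 1]", {
  cfg0 <- small_cfg(seed = 41)
  genome <- simulate_genome(cfg0)
  ann <- simulate_annotation(cfg0, genome)
  pd <- data.frame(gene_id = ann$genes$gene_id[1:2],
                   kind = c("UPR500", "GBR"), context = "CG",
                   delta_pp = c(40, 90))
  cfg <- small_cfg(seed = 41, planted_dm = pd)
  sim <- simulate_methylomes(cfg, genome, ann$genes)
  tr <- sim$truth
  t1 <- tr[tr$gene_id == pd$gene_id[1] & tr$kind == "UPR500" &
             tr$context == "CG", ]
  expect_equal(t1$true_level_mut - t1$true_level_wt, 0.40)
  expect_true(t1$planted)
  # UPR200 nests inside the planted UPR500 window, so it inherits the shift
  t200 <- tr[tr$gene_id == pd$gene_id[1] & tr$kind == "UPR200" &
               tr$context == "CG", ]
  expect_equal(t200$true_level_mut - t200$true_level_wt, 0.40)
  # +90 pp on a 0.24 baseline clamps at 1
  t2 <- tr[tr$gene_id == pd$gene_id[2] & tr$kind == "GBR" &
             tr$context == "CG", ]
  expect_equal(t2$true_level_mut, 1.0)
  # unplanted context untouched
  chh <- tr[tr$gene_id == pd$gene_id[1] & tr$kind == "UPR500" &
              tr$context == "CHH", ]
  expect_equal(chh$true_level_mut, chh$true_level_wt)
  expect_error(simulate_methylomes(
    small_cfg(seed = 41, planted_dm = data.frame(
      gene_id = "nope", kind = "GBR", context = "CG", delta_pp = 10)),
    genome, ann$genes), "unknown region")
})

test_that("estimated region levels converge to the truth", {
  cfg <- small_cfg(seed = 51, n_genes = 10L, chrom_length_bp = 40000L)
  genome <- simulate_genome(cfg)
  ann <- simulate_annotation(cfg, genome)
  sim <- simulate_methylomes(cfg, genome, ann$genes)
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  regs <- derive_regions(ann$genes, chrom_lengths)
  prof <- profile_methylation(filter_by_coverage(sim$wt), regs)
  j <- merge(prof, sim$truth, by = c("gene_id", "kind", "context"))
  j <- j[!is.na(j$level) & j$n_cytosines.x >= 10, ]
  expect_gt(nrow(j), 50)
  rmse <- sqrt(mean((j$level - j$true_level_wt)^2))
  expect_lt(rmse * 100, 3)   # within 3 percentage points
})

test_that("expression simulation is deterministic with exact noiseless ratios", {
  ids <- sprintf("SIMG%04d", 1:20)
  planted <- data.frame(gene_id = ids[1], ratio = 1.97)
  cfg <- small_cfg(seed = 61, planted_expr = planted, expr_noise_sigma = 0)
  s1 <- simulate_expression(cfg, ids)
  s2 <- simulate_expression(cfg, ids)
  expect_identical(s1, s2)
  out <- classify_expression_change(s1$expr)
  expect_equal(out$change[1], "up")
  expect_equal(out$ratio[1], 1.97)
  # ratio 1 everywhere with no noise: nothing is up or down
  cfg0 <- small_cfg(seed = 61, expr_noise_sigma = 0)
  out0 <- classify_expression_change(simulate_expression(cfg0, ids)$expr)
  expect_true(all(out0$change %in% c("unchanged", "not_expressed")))
  expect_error(simulate_expression(
    small_cfg(planted_expr = data.frame(gene_id = "zz", ratio = 2)), ids),
    "unknown gene")
})

test_that("null simulations give near-zero mean estimated delta", {
  cfg <- small_cfg(seed = 71, n_genes = 10L, chrom_length_bp = 40000L)
  genome <- simulate_genome(cfg)
  ann <- simulate_annotation(cfg, genome)
  sim <- simulate_methylomes(cfg, genome, ann$genes)
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  regs <- derive_regions(ann$genes, chrom_lengths)
  pw <- profile_methylation(filter_by_coverage(sim$wt), regs)
  pm <- profile_methylation(filter_by_coverage(sim$mut), regs)
  cmp <- compare_methylation(pw, pm)
  cg <- cmp[cmp$context == "CG" & !is.na(cmp$delta_pp), ]
  expect_lt(abs(mean(cg$delta_pp)), 2)
})
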