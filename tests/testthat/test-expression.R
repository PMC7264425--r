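test_that("fpkm follows the per-kilobase per-million definition", {
  expect_equal(fpkm(100, 1000, 1e7), 10)
  expect_equal(fpkm(0, 1234, 5e6), 0)
  expect_equal(fpkm(1, 500, 2e6), 1)
  expect_error(fpkm(10, 0, 1e6))
  expect_error(fpkm(-1, 100, 1e6))
  # linear in counts, inverse-linear in length and library size
  expect_equal(fpkm(200, 1000, 1e7), 2 * fpkm(100, 1000, 1e7))
  expect_equal(fpkm(100, 2000, 1e7), fpkm(100, 1000, 1e7) / 2)
  expect_equal(fpkm(100, 1000, 2e7), fpkm(100, 1000, 1e7) / 2)
})

test_that("expression changes classify on the ratio with an expression floor", {
  expr <- data.frame(
    gene_id = c("up197", "flat", "weak", "zero_wt", "down", "b_up", "b_down"),
    fpkm_wt = c(2.0, 2.0, 0.5, 0.0, 4.0, 2.0, 2.0),
    fpkm_mut = c(3.94, 1.9, 0.6, 1.5, 1.0, 2.2, 1.8))
  out <- classify_expression_change(expr)
  got <- setNames(out$change, out$gene_id)
  expect_equal(got[["up197"]], "up")          # ratio 1.97
  expect_equal(got[["flat"]], "unchanged")    # ratio 0.95
  expect_equal(got[["weak"]], "not_expressed")
  expect_equal(got[["zero_wt"]], "up")        # zero denominator rule
  expect_true(is.na(out$ratio[out$gene_id == "zero_wt"]))
  expect_equal(got[["down"]], "down")
  expect_equal(got[["b_up"]], "up")           # ratio exactly 1.1 inclusive
  expect_equal(got[["b_down"]], "down")       # ratio exactly 0.9 inclusive
  expect_error(classify_expression_change(
    data.frame(gene_id = "x", fpkm_wt = -1, fpkm_mut = 2)))
})

test_that("swapping genotypes with reciprocal thresholds mirrors labels", {
  set.seed(9)
  expr <- data.frame(gene_id = sprintf("g%03d", 1:200),
                     fpkm_wt = rlnorm(200, log(5), 1),
                     fpkm_mut = rlnorm(200, log(5), 1))
  fwd <- classify_expression_change(expr, up_ratio = 1.25, down_ratio = 0.8)
  swapped <- data.frame(gene_id = expr$gene_id, fpkm_wt = expr$fpkm_mut,
                        fpkm_mut = expr$fpkm_wt)
  rev <- classify_expression_change(swapped, up_ratio = 1 / 0.8,
                                    down_ratio = 1 / 1.25)
  expect_equal(rev$change == "up", fwd$change == "down")
  expect_equal(rev$change == "down", fwd$change == "up")
  expect_equal(rev$change == "not_expressed", fwd$change == "not_expressed")
})

test_that("BH adjustment matches an independent step-up loop", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_error(bh_adjust(c(0.5, 1.2)))
  expect_error(bh_adjust(c(0.5, -0.1)))
  # brute-force oracle: sort, scale by m/rank, enforce monotonicity from
  # the largest down, cap at 1, restore order
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
    pmin(adj, 1)[order(o)]
  }
  set.seed(13)
  for (i in 1:25) {
    p <- runif(sample(2:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("DE filter is strict on fold change, inclusive on FDR", {
  expect_true(apply_de_filter(2.5, 0.01))
  expect_false(apply_de_filter(2.0, 0.01))   # exactly twofold fails
  expect_true(apply_de_filter(0.3, 0.04))    # down direction
  expect_false(apply_de_filter(0.5, 0.04))   # exactly half fails
  expect_true(apply_de_filter(3, 0.05))      # FDR boundary passes
  expect_false(apply_de_filter(3, 0.051))
  expect_error(apply_de_filter(0, 0.01))
})

test_that("2^-ddCt reproduces worked folds and is shift-invariant", {
  expect_equal(ddct_fold_change(25, 20, 24, 20), 0.5)
  expect_equal(ddct_fold_change(22, 19, 22, 19), 1.0)
  expect_equal(ddct_fold_change(23, 20, 25, 20), 4.0)
  # replicate aggregation by condition means
  expect_equal(ddct_fold_change(c(24.5, 25.5), c(19, 21), 24, 20), 0.5)
  expect_error(ddct_fold_change(numeric(0), 20, 24, 20))
  expect_error(ddct_fold_change(25, 20, -24, 20))
  set.seed(17)
  for (i in 1:10) {
    ct <- runif(4, 15, 30); shift <- runif(1, 1, 5)
    expect_equal(ddct_fold_change(ct[1] + shift, ct[2] + shift,
                                  ct[3] + shift, ct[4] + shift),
                 ddct_fold_change(ct[1], ct[2], ct[3], ct[4]))
  }
})

test_that("long Ct tables round-trip and fold per transcript", {
  cfg <- sim_config(seed = 5)
  ct <- simulate_ct(cfg, c(t1 = 0.5, t2 = 4), noise_sd = 0)
  path <- tempfile(fileext = ".csv")
  data.table::fwrite(ct, path)
  back <- read_ct_table(path)
  folds <- ddct_table(back)
  expect_equal(setNames(folds$fold_change, folds$transcript_id),
               c(t1 = 0.5, t2 = 4))
  bad <- back[back$condition == "test", ]
  expect_error(ddct_table(bad), "two conditions")
})

test_that("FPKM table IO combines genotypes over the shared gene set", {
  wt <- data.frame(gene_id = c("a", "b", "c"), fpkm = c(1, 2, 3))
  mut <- data.frame(gene_id = c("b", "c", "d"), fpkm = c(5, 6, 7))
  comb <- combine_fpkm(wt, mut)
  expect_equal(comb$gene_id, c("b", "c"))
  expect_equal(comb$fpkm_mut, c(5, 6))
  path <- tempfile(fileext = ".tsv")
  data.table::fwrite(comb, path, sep = "\t")
  expect_equal(read_fpkm_table(path), comb, ignore_attr = TRUE)
  expect_error(read_fpkm_table({
    p <- tempfile(); writeLines("x\ty\n1\t2", p); p
  }), "columns")
})

test_that("planted expression ratios are recovered as 'up' labels", {
  ids <- sprintf("g%04d", 1:500)
  planted <- data.frame(gene_id = ids[1:50], ratio = 1.5)
  cfg <- sim_config(seed = 99, n_genes = 500, planted_expr = planted,
                    expr_noise_sigma = 0.05)
  sim <- simulate_expression(cfg, ids)
  out <- classify_expression_change(sim$expr)
  recall <- mean(out$change[out$gene_id %in% planted$gene_id] == "up")
  expect_gte(recall, 0.95)
})
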