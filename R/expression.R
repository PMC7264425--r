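#' FPKM from fragment counts
#'
#' Expected fragments per kilobase of transcript per million fragments
#' sequenced: `count * 1e9 / (length_bp * total_fragments)`.
#'
#' @param fragment_count Non-negative fragment counts.
#' @param transcript_length_bp Positive transcript lengths in bp.
#' @param total_mapped_fragments Positive library size (mapped fragments).
#' @return FPKM values.
#' @export
fpkm <- function(fragment_count, transcript_length_bp,
                 total_mapped_fragments) {
  if (any(fragment_count < 0)) stop("fragment_count must be non-negative")
  if (any(transcript_length_bp <= 0) || any(total_mapped_fragments <= 0))
    stop("transcript length and library size must be positive")
  fragment_count * 1e9 / (transcript_length_bp * total_mapped_fragments)
}

#' Classify per-gene expression changes from two-genotype FPKM values
#'
#' A gene is `not_expressed` when both genotypes are below `min_fpkm`
#' (default 1 FPKM).  Otherwise the mutant/wild-type FPKM ratio is
#' classified: `up` when the ratio is at least `up_ratio` (default 1.1),
#' `down` when at most `down_ratio` (default 0.9), `unchanged` in between.
#' A wild-type FPKM of exactly zero with an expressed mutant
#' (`fpkm_mut >= min_fpkm`) is labelled `up` with an undefined (`NA`)
#' ratio.
#'
#' @param expr A `data.frame` with columns `gene_id`, `fpkm_wt`, `fpkm_mut`.
#' @param min_fpkm Expression floor in FPKM.
#' @param up_ratio,down_ratio Ratio thresholds, `0 < down_ratio < 1 <
#'   up_ratio`; both are inclusive.
#' @return `expr` with added columns `ratio` (mut/wt, `NA` when
#'   `fpkm_wt == 0`) and `change` over
#'   `{"up","down","unchanged","not_expressed"}`.
#' @export
classify_expression_change <- function(expr, min_fpkm = 1.0,
                                       up_ratio = 1.1, down_ratio = 0.9) {
  stopifnot(is.data.frame(expr),
            all(c("gene_id", "fpkm_wt", "fpkm_mut") %in% names(expr)),
            down_ratio > 0, down_ratio < 1, up_ratio > 1)
  wt <- expr$fpkm_wt; mut <- expr$fpkm_mut
  if (any(wt < 0, na.rm = TRUE) || any(mut < 0, na.rm = TRUE))
    stop("FPKM values must be non-negative")
  ratio <- ifelse(wt > 0, mut / wt, NA_real_)
  change <- rep("unchanged", nrow(expr))
  change[!is.na(ratio) & ratio >= up_ratio] <- "up"
  change[!is.na(ratio) & ratio <= down_ratio] <- "down"
  change[wt == 0 & mut >= min_fpkm] <- "up"
  change[pmax(wt, mut) < min_fpkm] <- "not_expressed"
  out <- as.data.frame(expr)
  out$ratio <- ratio
  out$change <- change
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating front-end over `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues P-values in \[0, 1\].
#' @return Adjusted values (same order), capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Differential-expression filter on fold change and FDR
#'
#' True for genes with a more-than-`fc_threshold`-fold change in either
#' direction (strict: exactly twofold fails the default filter) and an
#' adjusted p-value at most `fdr_threshold` (inclusive).
#'
#' @param fold_change Positive fold changes (mut/wt).
#' @param fdr Adjusted p-values.
#' @param fc_threshold Fold-change cutoff (default 2).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return Logical vector.
#' @export
apply_de_filter <- function(fold_change, fdr, fc_threshold = 2.0,
                            fdr_threshold = 0.05) {
  if (any(fold_change <= 0)) stop("fold changes must be positive")
  (fold_change > fc_threshold | fold_change < 1 / fc_threshold) &
    fdr <= fdr_threshold
}

#' Relative quantification by the 2^-ddCt method
#'
#' Livak's comparative-Ct fold change.  Replicate Ct values are averaged per
#' condition before differencing: `dCt_test = mean(ct_target_test) -
#' mean(ct_ref_test)`, likewise for the control, and the fold change is
#' `2^-(dCt_test - dCt_ctrl)`.  Adding a constant to all four Ct means
#' leaves the fold change unchanged.
#'
#' @param ct_target_test,ct_ref_test,ct_target_ctrl,ct_ref_ctrl Numeric
#'   vectors of replicate Ct values (cycles); each needs at least one
#'   finite, positive replicate.
#' @return The fold change (scalar).
#' @export
ddct_fold_change <- function(ct_target_test, ct_ref_test,
                             ct_target_ctrl, ct_ref_ctrl) {
  vals <- list(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl)
  if (any(vapply(vals, length, 1L) == 0L))
    stop("each condition/role needs at least one Ct replicate")
  if (!all(vapply(vals, function(v) all(is.finite(v) & v > 0), TRUE)))
    stop("Ct values must be finite and positive")
  dct_test <- mean(ct_target_test) - mean(ct_ref_test)
  dct_ctrl <- mean(ct_target_ctrl) - mean(ct_ref_ctrl)
  2^-(dct_test - dct_ctrl)
}

#' Read a qPCR Ct table (CSV)
#'
#' Expected columns: `transcript_id`, `condition`, `role`
#' (`"target"`/`"reference"`), `replicate`, `ct`.
#'
#' @param path CSV path.
#' @return A `data.frame`.
#' @export
read_ct_table <- function(path) {
  ct <- as.data.frame(data.table::fread(path))
  need <- c("transcript_id", "condition", "role", "replicate", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  if (!all(ct$role %in% c("target", "reference")))
    stop("role must be 'target' or 'reference'")
  ct
}

#' Per-transcript 2^-ddCt fold changes from a long Ct table
#'
#' @param ct Table as from [read_ct_table()]; exactly two conditions, one of
#'   which is `control_condition`.
#' @param control_condition Name of the control (calibrator) condition.
#' @return A `data.frame` with `transcript_id` and `fold_change`.
#' @export
ddct_table <- function(ct, control_condition = "control") {
  conds <- unique(ct$condition)
  if (length(conds) != 2L || !control_condition %in% conds)
    stop("Ct table must contain exactly two conditions including '",
         control_condition, "'")
  test_condition <- setdiff(conds, control_condition)
  pick <- function(d, cond, rl) d$ct[d$condition == cond & d$role == rl]
  ids <- unique(ct$transcript_id)
  fold <- vapply(ids, function(id) {
    d <- ct[ct$transcript_id == id, , drop = FALSE]
    ddct_fold_change(pick(d, test_condition, "target"),
                     pick(d, test_condition, "reference"),
                     pick(d, control_condition, "target"),
                     pick(d, control_condition, "reference"))
  }, 1.0)
  data.frame(transcript_id = ids, fold_change = unname(fold),
             stringsAsFactors = FALSE)
}

#' Read a per-gene FPKM table (TSV)
#'
#' Accepts a single-genotype table (`gene_id`, `fpkm`) or a combined one
#' (`gene_id`, `fpkm_wt`, `fpkm_mut`).
#'
#' @param path TSV path.
#' @return A `data.frame`.
#' @export
read_fpkm_table <- function(path) {
  x <- as.data.frame(data.table::fread(path, sep = "\t"))
  ok <- all(c("gene_id", "fpkm") %in% names(x)) ||
    all(c("gene_id", "fpkm_wt", "fpkm_mut") %in% names(x))
  if (!ok)
    stop("FPKM table must have columns (gene_id, fpkm) or ",
         "(gene_id, fpkm_wt, fpkm_mut)")
  x
}

#' Combine two single-genotype FPKM tables
#'
#' @param wt,mut Tables with columns `gene_id`, `fpkm`.
#' @return Combined `data.frame` (`gene_id`, `fpkm_wt`, `fpkm_mut`) over the
#'   intersection of gene IDs.
#' @export
combine_fpkm <- function(wt, mut) {
  stopifnot(all(c("gene_id", "fpkm") %in% names(wt)),
            all(c("gene_id", "fpkm") %in% names(mut)))
  out <- merge(wt[, c("gene_id", "fpkm")], mut[, c("gene_id", "fpkm")],
               by = "gene_id", suffixes = c("_wt", "_mut"))
  names(out) <- c("gene_id", "fpkm_wt", "fpkm_mut")
  out
}
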