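#' Classify methylation levels into high/low groups
#'
#' Genes are split on their methylation level at the 0.1 boundary:
#' group 1 holds levels strictly greater than 0.1, group 2 the rest
#' (a level of exactly 0.1 falls in group 2, since group 1 is defined
#' strictly).  Undefined levels pass through as `NA`.
#'
#' @param level Numeric vector of methylation fractions (or `NA`).
#' @param boundary Group boundary (default 0.1).
#' @return Character vector over `{"group1","group2", NA}`.
#' @export
classify_group <- function(level, boundary = 0.1) {
  ifelse(is.na(level), NA_character_,
         ifelse(level > boundary, "group1", "group2"))
}

#' Mutant-minus-wild-type methylation difference in percentage points
#'
#' @param level_mut,level_wt Methylation fractions (or `NA`).
#' @return `100 * (level_mut - level_wt)`; `NA` when either input is `NA`.
#' @export
methylation_delta <- function(level_mut, level_wt) {
  100 * (level_mut - level_wt)
}

#' Call hyper-/hypomethylation from a percentage-point difference
#'
#' Calls are made on absolute percentage-point differences, not ratios, and
#' the threshold is inclusive: a difference of exactly `+threshold_pp` is
#' hyper, exactly `-threshold_pp` hypo.
#'
#' @param delta_pp Differences in percentage points (or `NA`).
#' @param threshold_pp Positive threshold in percentage points.
#' @return Character vector over `{"hyper","hypo","unchanged", NA}`.
#' @export
call_differential <- function(delta_pp, threshold_pp) {
  stopifnot(is.numeric(threshold_pp), length(threshold_pp) == 1L,
            threshold_pp > 0)
  ifelse(is.na(delta_pp), NA_character_,
         ifelse(delta_pp >= threshold_pp, "hyper",
                ifelse(delta_pp <= -threshold_pp, "hypo", "unchanged")))
}

#' Compare two genotype methylation profiles
#'
#' Joins wild-type and mutant profiles on (gene, kind, context), computes the
#' percentage-point difference and calls hyper/hypo/unchanged using a
#' per-kind threshold: `upr_threshold_pp` (default 10) for the upstream
#' windows and `gbr_threshold_pp` (default 5) for gene bodies.  Genes
#' undefined in either genotype are reported with an `NA` call, never
#' dropped.
#'
#' @param profile_wt,profile_mut Profiles from [profile_methylation()].
#' @param upr_threshold_pp,gbr_threshold_pp Call thresholds in percentage
#'   points.
#' @return A `data.frame` with `gene_id`, `kind`, `context`, `level_wt`,
#'   `level_mut`, `delta_pp`, `call`.
#' @export
compare_methylation <- function(profile_wt, profile_mut,
                                upr_threshold_pp = 10,
                                gbr_threshold_pp = 5) {
  wt <- as.data.table(profile_wt)[, .(gene_id, kind, context,
                                      level_wt = level)]
  mut <- as.data.table(profile_mut)[, .(gene_id, kind, context,
                                        level_mut = level)]
  cmp <- merge(wt, mut, by = c("gene_id", "kind", "context"), all = TRUE,
               sort = FALSE)
  cmp[, delta_pp := methylation_delta(level_mut, level_wt)]
  thr <- ifelse(.is_upr(cmp$kind), upr_threshold_pp, gbr_threshold_pp)
  cmp[, call := NA_character_]
  for (t in unique(thr)) {
    i <- which(thr == t)
    data.table::set(cmp, i, "call", call_differential(cmp$delta_pp[i], t))
  }
  as.data.frame(cmp)
}

#' Group-1/group-2 proportions over a set of levels
#'
#' Fractions are taken over genes with defined levels only.
#'
#' @param levels Numeric vector of methylation fractions (or `NA`).
#' @param boundary Group boundary passed to [classify_group()].
#' @return A list with `group1_frac`, `group2_frac` (both `NA` when nothing
#'   is defined) and `n_defined`.
#' @export
group_proportions <- function(levels, boundary = 0.1) {
  g <- classify_group(levels, boundary)
  n <- sum(!is.na(g))
  if (n == 0L)
    return(list(group1_frac = NA_real_, group2_frac = NA_real_,
                n_defined = 0L))
  list(group1_frac = sum(g == "group1", na.rm = TRUE) / n,
       group2_frac = sum(g == "group2", na.rm = TRUE) / n,
       n_defined = n)
}

#' Gene-by-genotype methylation level matrix for one region kind and context
#'
#' @param profile_wt,profile_mut Profiles from [profile_methylation()]; both
#'   must cover the same gene list for the requested kind.
#' @param kind Region kind (`"UPR200"`, `"UPR500"`, `"GBR"`).
#' @param context Sequence context.
#' @param genotype_names Column names (default `c("wt","mut")`).
#' @return A numeric matrix (genes x 2) with `NA` for undefined levels; row
#'   order follows `profile_wt`.
#' @export
heatmap_matrix <- function(profile_wt, profile_mut, kind, context,
                           genotype_names = c("wt", "mut")) {
  stopifnot(kind %in% REGION_KINDS, context %in% METH_CONTEXTS,
            length(genotype_names) == 2L)
  pick <- function(p) {
    p <- p[p$kind == kind & p$context == context, , drop = FALSE]
    stats::setNames(p$level, p$gene_id)
  }
  a <- pick(as.data.frame(profile_wt)); b <- pick(as.data.frame(profile_mut))
  if (length(a) != length(b) || !setequal(names(a), names(b)))
    stop("gene-list mismatch between genotype profiles")
  m <- cbind(a, b[names(a)])
  colnames(m) <- genotype_names
  m
}

#' Render a methylation level heatmap
#'
#' Thin wrapper over pheatmap with clustering disabled, so row order follows
#' the input gene list.
#'
#' @param mat Matrix from [heatmap_matrix()].
#' @param file Optional PNG path; `NULL` draws to the active device.
#' @param ... Passed on to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_methylation_heatmap <- function(mat, file = NULL, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_methylation_heatmap requires the 'pheatmap' package")
  args <- list(mat = mat, cluster_rows = FALSE, cluster_cols = FALSE, ...)
  if (!is.null(file)) args$filename <- file
  invisible(do.call(pheatmap::pheatmap, args))
}
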