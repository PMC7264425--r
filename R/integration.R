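#' Cross-mutant consistency of expression-change directions
#'
#' Partitions the union of gene universes of two mutant-vs-wild-type label
#' maps into genes up in both, down in both, oppositely directed, and
#' everything else (including genes unchanged, unexpressed, or missing from
#' either map).  The four sets are disjoint and exhaustive.
#'
#' @param labels_mut1,labels_mut2 Named character vectors mapping gene IDs
#'   to change labels (`"up"`, `"down"`, ...).
#' @return A list of character vectors: `up_both`, `down_both`,
#'   `discordant`, `other`.
#' @export
consistent_direction_genes <- function(labels_mut1, labels_mut2) {
  stopifnot(!is.null(names(labels_mut1)), !is.null(names(labels_mut2)))
  universe <- union(names(labels_mut1), names(labels_mut2))
  l1 <- unname(labels_mut1[universe]); l2 <- unname(labels_mut2[universe])
  dir1 <- !is.na(l1) & l1 %in% c("up", "down")
  dir2 <- !is.na(l2) & l2 %in% c("up", "down")
  both <- dir1 & dir2
  up_both <- universe[both & l1 == "up" & l2 == "up"]
  down_both <- universe[both & l1 == "down" & l2 == "down"]
  discordant <- universe[both & l1 != l2]
  other <- setdiff(universe, c(up_both, down_both, discordant))
  list(up_both = up_both, down_both = down_both,
       discordant = discordant, other = other)
}

#' Link differential-methylation calls to expression changes
#'
#' For one (region kind, context) pair, joins hyper/hypo calls with
#' expression-change labels over the intersection of gene universes and
#' assigns the link direction: `negative` for (hyper, down) or (hypo, up),
#' `positive` for (hyper, up) or (hypo, down), `none` otherwise.  Genes
#' present in only one input are counted in the `n_missing` attribute, never
#' imputed.
#'
#' @param dm_calls Comparison table from [compare_methylation()] (columns
#'   `gene_id`, `kind`, `context`, `call`).
#' @param expr_changes Table with `gene_id` and `change` (e.g. from
#'   [classify_expression_change()]).
#' @param kind,context Region kind and sequence context to link.
#' @return A `data.frame` with `gene_id`, `kind`, `context`, `dm_call`,
#'   `expr_change`, `link`; attribute `n_missing` holds the counts of genes
#'   seen in only one input.
#' @export
methylation_expression_links <- function(dm_calls, expr_changes, kind,
                                         context) {
  stopifnot(kind %in% REGION_KINDS, context %in% METH_CONTEXTS)
  dm <- as.data.frame(dm_calls)
  dm <- dm[dm$kind == kind & dm$context == context, , drop = FALSE]
  ex <- as.data.frame(expr_changes)
  shared <- intersect(dm$gene_id, ex$gene_id)
  dmc <- stats::setNames(dm$call, dm$gene_id)[shared]
  exc <- stats::setNames(ex$change, ex$gene_id)[shared]
  link <- rep("none", length(shared))
  hyper <- !is.na(dmc) & dmc == "hyper"
  hypo <- !is.na(dmc) & dmc == "hypo"
  up <- !is.na(exc) & exc == "up"
  down <- !is.na(exc) & exc == "down"
  link[(hyper & down) | (hypo & up)] <- "negative"
  link[(hyper & up) | (hypo & down)] <- "positive"
  out <- data.frame(gene_id = shared, kind = kind, context = context,
                    dm_call = unname(dmc), expr_change = unname(exc),
                    link = link, stringsAsFactors = FALSE)
  attr(out, "n_missing") <- list(
    dm_only = length(setdiff(dm$gene_id, ex$gene_id)),
    expr_only = length(setdiff(ex$gene_id, dm$gene_id)))
  out
}

#' Summarise link counts
#'
#' @param links Table from [methylation_expression_links()].
#' @return A `data.frame` of counts by `dm_call`, `expr_change` and `link`.
#' @export
link_summary <- function(links) {
  dt <- as.data.table(links)
  as.data.frame(dt[, .N, by = .(dm_call, expr_change, link)])
}
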