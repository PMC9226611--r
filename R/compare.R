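# Cross-condition set analysis over consensus essentiality calls: per-
# condition summaries, the core essential genome, UpSet-style membership
# patterns, and condition-specific essential sets. "Essential" here always
# means consensus Essential (not GrowthDefect, not Uncertain).

#' Genes with consensus Essential in a condition
#'
#' @param calls A `tn_calls` data.frame from [classify_replicates].
#' @return Character vector of gene ids.
#' @export
essential_set <- function(calls) {
  calls$gene_id[calls$consensus == "Essential"]
}

#' Per-condition category counts
#'
#' Counts consensus calls in the five reporting categories (Essential,
#' GrowthDefect, NonEssential, GrowthAdvantage, Uncertain); genes excluded
#' by the TA-site filters are reported separately.
#'
#' @param calls A `tn_calls` data.frame.
#' @return Named integer vector with the five category counts and
#'   `Excluded`.
#' @export
summarize_condition <- function(calls) {
  cats <- c(.categories, "Uncertain", "Excluded")
  out <- vapply(cats, function(k) sum(calls$consensus == k), integer(1))
  out
}

#' Summary table over conditions
#'
#' One row per condition in the layout of a per-library essentiality-call
#' distribution table.
#'
#' @param calls_list Named list of `tn_calls`, one per condition.
#' @return data.frame with `condition` and one column per category.
#' @export
summarize_conditions <- function(calls_list) {
  stopifnot(length(calls_list) >= 1L, !is.null(names(calls_list)))
  rows <- lapply(calls_list, summarize_condition)
  out <- as.data.frame(do.call(rbind, rows))
  cbind(condition = names(calls_list), out, row.names = NULL)
}

#' Core essential genome
#'
#' Genes with consensus Essential in every condition.
#'
#' @param calls_list list of `tn_calls` (at least 2 conditions).
#' @return Character vector of gene ids.
#' @export
core_essential <- function(calls_list) {
  stopifnot(length(calls_list) >= 2L)
  Reduce(intersect, lapply(calls_list, essential_set))
}

#' UpSet-style membership patterns of essential genes
#'
#' Every gene essential in at least one condition is assigned to exactly one
#' membership pattern (which conditions call it essential); pattern counts
#' therefore partition the union of essential sets.
#'
#' @param calls_list Named list of `tn_calls`.
#' @return data.frame with one logical column per condition, `pattern`
#'   (bit string in condition order), `n`, and `genes` (list column).
#' @export
membership_matrix <- function(calls_list) {
  stopifnot(length(calls_list) >= 1L, !is.null(names(calls_list)))
  sets <- lapply(calls_list, essential_set)
  all_genes <- sort(unique(unlist(sets)))
  if (length(all_genes) == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(logical(0)), length(sets)), names(sets)))
    out$pattern <- character(0); out$n <- integer(0)
    out$genes <- list()
    return(out)
  }
  mem <- vapply(sets, function(s) all_genes %in% s,
                logical(length(all_genes)))
  mem <- matrix(mem, nrow = length(all_genes),
                dimnames = list(all_genes, names(sets)))
  pattern <- apply(mem, 1L, function(b) paste(as.integer(b), collapse = ""))
  split_genes <- split(all_genes, pattern)
  pats <- names(split_genes)
  bits <- do.call(rbind, lapply(strsplit(pats, ""),
                                function(b) as.logical(as.integer(b))))
  colnames(bits) <- names(sets)
  out <- as.data.frame(bits)
  out$pattern <- pats
  out$n <- lengths(split_genes)
  out$genes <- unname(split_genes)
  out[order(-out$n), , drop = FALSE]
}

#' Condition-specific essential genes
#'
#' Genes with consensus Essential in every target condition and not
#' Essential in any background condition (a gene Uncertain or GrowthDefect
#' in a background condition counts as not essential there).
#'
#' @param calls_list Named list of `tn_calls` covering all conditions.
#' @param target,background Disjoint character vectors of condition names.
#' @return Character vector of gene ids.
#' @export
condition_specific <- function(calls_list, target, background) {
  stopifnot(!is.null(names(calls_list)))
  if (length(intersect(target, background)))
    stop("target and background conditions overlap: ",
         paste(intersect(target, background), collapse = ", "))
  missing <- setdiff(c(target, background), names(calls_list))
  if (length(missing))
    stop("unknown condition(s): ", paste(missing, collapse = ", "))
  if (length(target) == 0L) stop("at least one target condition required")
  ess <- Reduce(intersect, lapply(calls_list[target], essential_set))
  for (b in background)
    ess <- setdiff(ess, essential_set(calls_list[[b]]))
  ess
}
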