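# Essentiality classification: per replicate, an outlier-trimmed normal fit
# of log2(normalized RpK) across genes defines z-score categories; replicate
# calls are combined by unanimity.

.categories <- c("Essential", "GrowthDefect", "NonEssential",
                 "GrowthAdvantage")

#' Classifier configuration
#'
#' Thresholds are in standard deviations of the fitted per-replicate
#' log2(normalized RpK) distribution: genes more than 3 SD below the mean
#' (below the interval covering 99.7% of a normal distribution) are
#' Essential, between 2 and 3 SD below are GrowthDefect, within 2 SD are
#' NonEssential, and more than 2 SD above are GrowthAdvantage. Outliers are
#' removed before the fit with one-pass Tukey fences at `k` interquartile
#' ranges beyond the quartiles (`k = 3`, the conventional "far out" fence).
#'
#' @param essential_z,defect_z,advantage_z Category boundaries (z-scores);
#'   must satisfy `essential_z < defect_z < 0 < advantage_z`.
#' @param outlier_method Currently only `"tukey"`.
#' @param tukey_k Fence multiplier.
#' @return list of class `tn_classifier_config`.
#' @export
classifier_config <- function(essential_z = -3, defect_z = -2,
                              advantage_z = 2, outlier_method = "tukey",
                              tukey_k = 3) {
  if (!(essential_z < defect_z && defect_z < 0 && 0 < advantage_z))
    stop("thresholds must satisfy essential_z < defect_z < 0 < advantage_z")
  outlier_method <- match.arg(outlier_method, "tukey")
  structure(list(essential_z = essential_z, defect_z = defect_z,
                 advantage_z = advantage_z, outlier_method = outlier_method,
                 tukey_k = tukey_k),
            class = "tn_classifier_config")
}

#' Remove outliers by one-pass Tukey fences
#'
#' Values outside `[Q1 - k*IQR, Q3 + k*IQR]` (quartiles by linear
#' interpolation, `stats::quantile` type 7) are removed in a single pass.
#' When the IQR is zero the fences collapse to the quartiles, so an
#' all-identical sample loses nothing.
#'
#' @param values Numeric vector of at least 4 finite values.
#' @param config A [classifier_config].
#' @return list with `retained` and `n_removed`.
#' @export
remove_outliers <- function(values, config = classifier_config()) {
  values <- values[is.finite(values)]
  if (length(values) < 4L)
    stop("need at least 4 finite values to assess outliers")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - config$tukey_k * iqr
  hi <- q[2] + config$tukey_k * iqr
  keep <- values >= lo & values <= hi
  list(retained = values[keep], n_removed = sum(!keep))
}

#' Fit a normal distribution to retained values
#'
#' The sample mean and sample standard deviation (n-1 denominator)
#' parameterize the normal curve against which genes are scored.
#'
#' @param retained Numeric vector, at least 2 values with nonzero variance.
#' @param n_outliers_removed Bookkeeping from [remove_outliers].
#' @return list of class `tn_fit` with `mean`, `sd`, `n_retained`,
#'   `n_outliers_removed`.
#' @export
fit_normal <- function(retained, n_outliers_removed = 0L) {
  if (length(retained) < 2L) stop("need at least 2 values to fit")
  m <- mean(retained)
  s <- stats::sd(retained)
  if (!is.finite(s) || s == 0) stop("zero variance: cannot fit a normal")
  structure(list(mean = m, sd = s, n_retained = length(retained),
                 n_outliers_removed = as.integer(n_outliers_removed)),
            class = "tn_fit")
}

#' Outlier-trimmed normal fit of one replicate
#'
#' @param values log2(normalized RpK) values of scoreable genes (NA and
#'   non-finite values, i.e. zero-read genes, are ignored).
#' @param config A [classifier_config].
#' @return A `tn_fit`.
#' @export
fit_replicate <- function(values, config = classifier_config()) {
  out <- remove_outliers(values, config)
  fit_normal(out$retained, out$n_removed)
}

#' @export
print.tn_fit <- function(x, ...) {
  cat(sprintf("tn_fit: mean %.4f, sd %.4f (n = %d, %d outliers removed)\n",
              x$mean, x$sd, x$n_retained, x$n_outliers_removed))
  invisible(x)
}

#' Classify genes of one replicate
#'
#' Genes with zero reads at unique first-95% sites are Essential
#' categorically (transposon insertion was never recovered, and log2(0) is
#' undefined); excluded genes are Excluded. All other genes are scored by
#' `z = (log2_norm_rpk - mean) / sd`: `z < essential_z` Essential,
#' `essential_z <= z < defect_z` GrowthDefect,
#' `defect_z <= z <= advantage_z` NonEssential, `z > advantage_z`
#' GrowthAdvantage (boundaries follow the strict/non-strict reading of
#' "less than" / "within" / "greater than").
#'
#' @param counts A `tn_gene_counts` data.frame (one replicate).
#' @param fit A `tn_fit` for that replicate.
#' @param config A [classifier_config].
#' @return data.frame `gene_id`, `z`, `category`.
#' @export
classify_genes <- function(counts, fit, config = classifier_config()) {
  stopifnot(inherits(fit, "tn_fit"))
  z <- (counts$log2_norm_rpk - fit$mean) / fit$sd
  category <- ifelse(z < config$essential_z, "Essential",
              ifelse(z < config$defect_z, "GrowthDefect",
              ifelse(z <= config$advantage_z, "NonEssential",
                     "GrowthAdvantage")))
  category[counts$raw_reads == 0L] <- "Essential"
  z[counts$raw_reads == 0L] <- -Inf
  category[counts$excluded != "none"] <- "Excluded"
  z[counts$excluded != "none"] <- NA_real_
  data.frame(gene_id = counts$gene_id, z = z, category = category,
             stringsAsFactors = FALSE)
}

#' Classify a single gene value
#'
#' @param value log2(normalized RpK), ignored when `zero_reads` is TRUE.
#' @param fit A `tn_fit`.
#' @param config A [classifier_config].
#' @param zero_reads TRUE for a gene with no recovered insertions.
#' @return Category string.
#' @export
classify_gene <- function(value, fit, config = classifier_config(),
                          zero_reads = FALSE) {
  if (zero_reads) return("Essential")
  z <- (value - fit$mean) / fit$sd
  if (z < config$essential_z) "Essential"
  else if (z < config$defect_z) "GrowthDefect"
  else if (z <= config$advantage_z) "NonEssential"
  else "GrowthAdvantage"
}

#' Replicate consensus call
#'
#' Unanimous replicate categories give that category; any disagreement gives
#' `Uncertain`. Order-invariant.
#'
#' @param categories Character vector of per-replicate categories (length
#'   at least 1).
#' @return Consensus category string.
#' @export
consensus_call <- function(categories) {
  if (length(categories) == 0L) stop("no replicate categories")
  u <- unique(categories)
  if (length(u) == 1L) u else "Uncertain"
}

#' Classify all replicates of a condition and form the consensus
#'
#' Fits each replicate independently (outlier-trimmed normal on that
#' replicate's finite log2 values), classifies every gene per replicate, and
#' combines calls by unanimity; disagreement yields `Uncertain`, and genes
#' excluded by the TA-site filters are `Excluded`.
#'
#' @param counts_list list of `tn_gene_counts`, one per replicate (same gene
#'   set and order).
#' @param config A [classifier_config].
#' @param condition Optional condition name stored on the result.
#' @return A `tn_calls` data.frame: `gene_id`, per-replicate `z.<i>` and
#'   `category.<i>` columns, and `consensus`; fits in
#'   `attr(, "fits")`.
#' @export
classify_replicates <- function(counts_list, config = classifier_config(),
                                condition = NULL) {
  stopifnot(length(counts_list) >= 1L)
  gene_id <- counts_list[[1L]]$gene_id
  for (cc in counts_list)
    if (!identical(cc$gene_id, gene_id))
      stop("replicates must cover the same genes in the same order")
  fits <- lapply(counts_list, function(cc)
    fit_replicate(cc$log2_norm_rpk, config))
  percat <- mapply(function(cc, f) classify_genes(cc, f, config),
                   counts_list, fits, SIMPLIFY = FALSE)
  out <- data.frame(gene_id = gene_id, stringsAsFactors = FALSE)
  for (i in seq_along(percat)) {
    out[[paste0("z.", i)]] <- percat[[i]]$z
    out[[paste0("category.", i)]] <- percat[[i]]$category
  }
  catmat <- do.call(cbind, lapply(percat, `[[`, "category"))
  out$consensus <- apply(catmat, 1L, consensus_call)
  out$consensus[counts_list[[1L]]$excluded != "none"] <- "Excluded"
  class(out) <- c("tn_calls", class(out))
  attr(out, "fits") <- fits
  attr(out, "condition") <- condition
  out
}
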