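# Discrimination metrics: rank-based AUROC, site-size-weighted average
# AUROC, and forgetting-trajectory summaries.

#' Area under the ROC curve (rank statistic, midrank ties)
#'
#' Computes the probability that a uniformly random positive record receives
#' a higher score than a uniformly random negative one, crediting ties 1/2
#' (the Mann-Whitney formulation). Exact, so a brute-force pairwise count
#' gives the identical value.
#'
#' @param scores numeric vector of scores (higher = more positive)
#' @param labels 0/1 vector, both classes present
#' @return AUROC in `[0, 1]`
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("auroc requires both classes to be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Site-size-weighted average AUROC
#'
#' Aggregates per-institution AUROCs as `sum_i (N_i / N) * AUROC_i` with
#' `N = sum_i N_i`.
#'
#' @param site_metrics list of entries with fields `site_id`, `n`, `auroc`,
#'   or a data.frame with columns `n` and `auroc`
#' @return weighted average AUROC
#' @export
weighted_auroc <- function(site_metrics) {
  if (is.data.frame(site_metrics)) {
    n <- site_metrics$n; a <- site_metrics$auroc
  } else {
    stopifnot(length(site_metrics) >= 1)
    n <- vapply(site_metrics, function(m) m$n, numeric(1))
    a <- vapply(site_metrics, function(m) m$auroc, numeric(1))
  }
  stopifnot(all(n >= 1))
  sum(n / sum(n) * a)
}

#' Per-site forgetting summary of a training trajectory
#'
#' For a stages x sites matrix of AUROCs, reports each site's peak value
#' over stages, its final-stage value, and the drop `peak - final` (always
#' nonnegative), the quantity that catastrophic forgetting inflates.
#'
#' @param stage_metrics numeric matrix, rows = training stages in order,
#'   columns = sites
#' @return data.frame with columns `site`, `peak`, `final`, `drop`
#' @export
forgetting_trajectory <- function(stage_metrics) {
  stage_metrics <- as.matrix(stage_metrics)
  sites <- colnames(stage_metrics)
  if (is.null(sites)) sites <- as.character(seq_len(ncol(stage_metrics)))
  peak <- apply(stage_metrics, 2, max)
  final <- stage_metrics[nrow(stage_metrics), ]
  data.frame(site = sites, peak = as.numeric(peak),
             final = as.numeric(final),
             drop = as.numeric(peak - final), row.names = NULL)
}

# append one metric record to a JSON-lines log (connection-free, append mode)
log_metric <- function(path, record) {
  if (is.null(path)) return(invisible(NULL))
  cat(jsonlite::toJSON(record, auto_unbox = TRUE), "\n",
      file = path, append = TRUE, sep = "")
  invisible(NULL)
}
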