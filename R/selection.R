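# Reproducibility-aware feature filtering and minimum-redundancy
# maximum-relevance (mRMR) selection.

#' Filter candidate features by reproducibility and univariate prognosis
#'
#' Ordered filters, applied to training data only:
#' 1. reproducibility: keep features whose generalized CCC in `ccc_lookup`
#'    is `>= ccc_threshold` (a threshold of 0 admits every feature; features
#'    absent from the lookup fail any positive threshold and are logged);
#' 2. discrimination: orient each feature (negate if raw C-index < 0.5) and
#'    keep oriented C-index `>= c_min`;
#' 3. significance: keep features whose univariate Cox Wald p is
#'    `< p_max`; fits that fail are excluded.
#'
#' The CCC lookup comes from an external reproducibility study, so applying
#' it outside the cross-validation folds does not leak outcome information.
#'
#' @param X Feature matrix (training subjects x features), columns named by
#'   feature id.
#' @param time,event Training survival outcome.
#' @param ccc_lookup Named numeric vector of generalized CCCs keyed by
#'   feature id.
#' @param ccc_threshold,c_min,p_max Filter parameters.
#' @return List: `features` (surviving ids), `sign` (orientation per
#'   survivor), `cindex` (oriented C per survivor), `counts` (per-stage
#'   survivor counts).
#' @export
filter_features <- function(X, time, event, ccc_lookup = NULL,
                            ccc_threshold = 0, c_min = 0.55, p_max = 0.1) {
  ids <- colnames(X)
  counts <- c(input = length(ids))
  if (ccc_threshold > 0) {
    ccc <- ccc_lookup[ids]
    keep <- !is.na(ccc) & ccc >= ccc_threshold
    if (any(is.na(ccc)))
      message(sprintf("filter_features: %d feature(s) missing from CCC table", sum(is.na(ccc))))
    ids <- ids[keep]
  }
  counts <- c(counts, ccc = length(ids))
  if (length(ids) == 0)
    return(list(features = character(0), sign = numeric(0),
                cindex = numeric(0), counts = c(counts, cindex = 0L, cox = 0L)))
  craw <- cindex_batch(X[, ids, drop = FALSE], time, event)
  sgn <- ifelse(craw < 0.5, -1, 1)
  cori <- ifelse(craw < 0.5, 1 - craw, craw)
  ok <- !is.na(cori) & cori >= c_min
  ids <- ids[ok]; sgn <- sgn[ok]; cori <- cori[ok]
  counts <- c(counts, cindex = length(ids))
  if (length(ids) == 0)
    return(list(features = ids, sign = sgn, cindex = cori,
                counts = c(counts, cox = 0L)))
  pvals <- vapply(seq_along(ids), function(k) {
    res <- tryCatch(univariate_cox(sgn[k] * X[, ids[k]], time, event),
                    error = function(e) list(p = NA_real_))
    res$p
  }, numeric(1))
  ok <- !is.na(pvals) & pvals < p_max
  ids <- ids[ok]; sgn <- sgn[ok]; cori <- cori[ok]
  counts <- c(counts, cox = length(ids))
  list(features = ids, sign = stats::setNames(sgn, ids),
       cindex = stats::setNames(cori, ids), counts = counts)
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy forward selection for right-censored outcomes: relevance of a
#' feature is its oriented univariate C-index minus 0.5; redundancy against
#' the already-selected set is the mean absolute Pearson correlation; at
#' each step the feature maximizing relevance minus mean redundancy (the
#' difference, MID, form) is added. The first pick is the most relevant
#' feature. If fewer than `k` candidates exist, all are returned.
#'
#' @param X Training feature matrix restricted to the candidates (oriented).
#' @param relevance Named relevance scores (oriented C-index - 0.5).
#' @param k Number of features to select (>= 1).
#' @return Character vector of selected ids, in selection order.
#' @export
mrmr_select <- function(X, relevance, k) {
  if (k < 1) abort("k must be >= 1")
  ids <- colnames(X)
  stopifnot(all(ids %in% names(relevance)))
  rel <- relevance[ids]
  if (length(ids) <= k) {
    return(ids[order(rel, decreasing = TRUE)])
  }
  selected <- character(0)
  red_sum <- stats::setNames(numeric(length(ids)), ids)
  remaining <- ids
  for (step in seq_len(k)) {
    if (step == 1) {
      pick <- remaining[which.max(rel[remaining])]
    } else {
      score <- rel[remaining] - red_sum[remaining] / length(selected)
      pick <- remaining[which.max(score)]
    }
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) == 0) break
    newcor <- abs(suppressWarnings(stats::cor(X[, remaining, drop = FALSE], X[, pick])))
    newcor[is.na(newcor)] <- 0  # zero-variance guard
    red_sum[remaining] <- red_sum[remaining] + newcor[, 1]
  }
  selected
}
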