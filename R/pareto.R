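# Joint reproducibility / prognosis reporting: Pareto efficiency and
# per-feature best-extractor tallies.

#' Pareto front over (CCC, C-index)
#'
#' A point is dominated if another point is at least as good on both
#' coordinates and strictly better on one; the front is the set of
#' non-dominated points. Exact ties (equal on both coordinates) do not
#' dominate each other, so duplicated optimal points are all retained.
#' Implemented as a sort-and-scan over CCC groups.
#'
#' @param points data.frame with numeric columns `ccc` and `cindex`
#'   (both maximized); other columns are carried through.
#' @return The efficient subset of `points` (rows with any non-finite
#'   coordinate are excluded with a warning).
#' @export
pareto_front <- function(points) {
  stopifnot(is.data.frame(points), all(c("ccc", "cindex") %in% names(points)))
  if (nrow(points) == 0) abort("empty point set")
  ok <- is.finite(points$ccc) & is.finite(points$cindex)
  if (any(!ok)) {
    warning(sprintf("excluding %d point(s) with non-finite coordinates", sum(!ok)))
    points <- points[ok, , drop = FALSE]
  }
  if (nrow(points) == 0) return(points)
  keep <- logical(nrow(points))
  ord <- order(-points$ccc, -points$cindex)
  best_higher <- -Inf  # max cindex among strictly larger ccc
  i <- 1
  while (i <= length(ord)) {
    grp <- ord[i]
    j <- i
    while (j < length(ord) && points$ccc[ord[j + 1]] == points$ccc[grp]) j <- j + 1
    g_idx <- ord[i:j]
    gmax <- points$cindex[g_idx[1]]  # sorted desc within group
    if (gmax > best_higher) keep[g_idx[points$cindex[g_idx] == gmax]] <- TRUE
    best_higher <- max(best_higher, gmax)
    i <- j + 1
  }
  points[sort(which(keep)), , drop = FALSE]
}

#' Joint per-feature extractor analysis
#'
#' Joins a reproducibility table and a univariate C-index table on
#' (feature, roi, extractor) and reports, per (feature, roi): the
#' extractor(s) with the highest CCC, the highest C-index, and the
#' per-feature Pareto-efficient extractor set; aggregated counts per
#' extractor and ROI (ties counted for every tied extractor); and the
#' global Pareto front over all (feature, extractor) points per ROI, with
#' duplicated (CCC, C) pairs flagged by a duplicate-group column.
#'
#' @param ccc_table data.frame `feature`, `roi`, `extractor`, `ccc`.
#' @param cindex_table data.frame `feature`, `roi`, `extractor`, `cindex`.
#' @return List: `per_feature`, `tallies`, `global_front`.
#' @export
per_feature_extractor_analysis <- function(ccc_table, cindex_table) {
  joined <- merge(ccc_table[, c("feature", "roi", "extractor", "ccc")],
                  cindex_table[, c("feature", "roi", "extractor", "cindex")],
                  by = c("feature", "roi", "extractor"))
  if (nrow(joined) == 0) abort("tables share no (feature, roi, extractor) keys")
  ok <- is.finite(joined$ccc) & is.finite(joined$cindex)
  skipped <- unique(joined$feature[!ok])
  if (length(skipped))
    message(sprintf("per_feature_extractor_analysis: skipped %d feature stream(s) with undefined values",
                    sum(!ok)))
  joined <- joined[ok, , drop = FALSE]
  grp <- interaction(joined$feature, joined$roi, drop = TRUE)
  per_feature <- do.call(rbind, lapply(split(joined, grp), function(g) {
    best_ccc <- g$extractor[g$ccc == max(g$ccc)]
    best_c <- g$extractor[g$cindex == max(g$cindex)]
    front <- pareto_front(g)$extractor
    data.frame(feature = g$feature[1], roi = g$roi[1],
               best_ccc = paste(sort(best_ccc), collapse = ","),
               best_cindex = paste(sort(best_c), collapse = ","),
               pareto = paste(sort(front), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(per_feature) <- NULL
  tally_one <- function(col) {
    long <- do.call(rbind, lapply(seq_len(nrow(per_feature)), function(i) {
      data.frame(roi = per_feature$roi[i],
                 extractor = strsplit(per_feature[[col]][i], ",")[[1]],
                 stringsAsFactors = FALSE)
    }))
    stats::aggregate(count ~ roi + extractor, cbind(long, count = 1), sum)
  }
  tallies <- merge(merge(
    stats::setNames(tally_one("best_ccc"), c("roi", "extractor", "n_best_ccc")),
    stats::setNames(tally_one("best_cindex"), c("roi", "extractor", "n_best_cindex")),
    by = c("roi", "extractor"), all = TRUE),
    stats::setNames(tally_one("pareto"), c("roi", "extractor", "n_pareto")),
    by = c("roi", "extractor"), all = TRUE)
  tallies[is.na(tallies)] <- 0
  global_front <- do.call(rbind, lapply(split(joined, joined$roi), function(g) {
    fr <- pareto_front(g)
    key <- paste(signif(fr$ccc, 12), signif(fr$cindex, 12))
    fr$dup_group <- match(key, unique(key))
    fr
  }))
  rownames(global_front) <- NULL
  list(per_feature = per_feature, tallies = tallies, global_front = global_front)
}
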