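# Hierarchical-clustering data for reproducibility / prognosis heat maps.

#' Row and column clustering for a feature-by-condition heat map
#'
#' Agglomerative clustering with Euclidean distance and Ward linkage on
#' both the rows (features) and columns (ROI x extractor conditions) of a
#' value matrix, as used to lay out CCC and C-index heat maps. Rows
#' containing any undefined value are dropped with a message. With fewer
#' than two rows (or columns) the identity ordering is returned and the
#' corresponding tree is `NULL`.
#'
#' @param m Numeric matrix with row and column names.
#' @param standardize_rows Center/scale rows before clustering (default
#'   FALSE; values like CCC and C-index are already on a common scale).
#' @return List with `row_order`, `col_order` (leaf orderings as labels),
#'   `row_tree`, `col_tree` (serializable lists: `merge`, `height`,
#'   `order`, `labels`) and the filtered matrix `m`.
#' @export
cluster_heatmap_data <- function(m, standardize_rows = FALSE) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("r", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  ok <- stats::complete.cases(m) & apply(is.finite(m), 1, all)
  if (any(!ok)) {
    message(sprintf("cluster_heatmap_data: dropped %d row(s) with undefined values", sum(!ok)))
    m <- m[ok, , drop = FALSE]
  }
  if (standardize_rows && nrow(m) > 0) {
    m <- t(scale(t(m)))
    m[!is.finite(m)] <- 0  # constant rows
  }
  tree_of <- function(x) {
    if (nrow(x) < 2) return(NULL)
    hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
    list(merge = hc$merge, height = hc$height, order = hc$order,
         labels = hc$labels)
  }
  rt <- tree_of(m)
  ct <- tree_of(t(m))
  list(row_order = if (is.null(rt)) rownames(m) else rownames(m)[rt$order],
       col_order = if (is.null(ct)) colnames(m) else colnames(m)[ct$order],
       row_tree = rt, col_tree = ct, m = m)
}
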