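# Harrell's concordance index and feature orientation.

# indices of comparable pairs (i, j): time_i < time_j and event_i = 1
comparable_pairs <- function(time, event) {
  comp <- outer(time, time, "<") & (event == 1)
  w <- which(comp, arr.ind = TRUE)
  list(i = w[, 1], j = w[, 2])
}

#' Harrell's C-index
#'
#' Over comparable pairs — (i, j) with `time_i < time_j` and subject i an
#' observed event — the proportion in which the earlier event carries the
#' higher risk score, with score ties credited 0.5.
#'
#' @param score Risk scores (higher = higher hazard).
#' @param time Follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return C-index in `[0, 1]`, or `NA` (with a warning) if there are no
#'   comparable pairs.
#' @export
harrell_cindex <- function(score, time, event) {
  n <- length(time)
  if (length(score) != n || length(event) != n) abort("inputs must have equal length")
  if (n < 2) abort("need at least 2 subjects")
  cp <- comparable_pairs(time, event)
  if (length(cp$i) == 0) {
    warning("no comparable pairs; C-index undefined")
    return(NA_real_)
  }
  si <- score[cp$i]; sj <- score[cp$j]
  (sum(si > sj) + 0.5 * sum(si == sj)) / length(si)
}

# batch C-index for the columns of a score matrix, reusing the pair set
cindex_batch <- function(scores, time, event) {
  cp <- comparable_pairs(time, event)
  if (length(cp$i) == 0) return(rep(NA_real_, ncol(scores)))
  m <- length(cp$i)
  vapply(seq_len(ncol(scores)), function(k) {
    si <- scores[cp$i, k]; sj <- scores[cp$j, k]
    (sum(si > sj) + 0.5 * sum(si == sj)) / m
  }, numeric(1))
}

#' Orient a feature to positive discrimination
#'
#' Features whose raw C-index is below 0.5 are negated so every oriented
#' C-index lies in `[0.5, 1]`. The orientation must be decided on training
#' data only; apply the returned `sign` to held-out data.
#'
#' @param values Feature values.
#' @param time,event Survival outcome (training data).
#' @return List with `values` (oriented), `cindex` (>= 0.5), `sign` (+1 or
#'   -1), or `NULL` (with a warning) if the C-index is undefined.
#' @export
orient_feature <- function(values, time, event) {
  c_raw <- harrell_cindex(values, time, event)
  if (is.na(c_raw)) {
    warning("C-index undefined; feature dropped")
    return(NULL)
  }
  if (c_raw < 0.5) {
    list(values = -values, cindex = 1 - c_raw, sign = -1)
  } else {
    list(values = values, cindex = c_raw, sign = 1)
  }
}
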