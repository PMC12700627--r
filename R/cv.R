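# Repeated, event-stratified k-fold cross-validation of the
# reproducibility-thresholded Cox modelling procedure, and the full
# experiment grid over (feature set, CCC threshold, feature count).

#' Cross-validation configuration
#'
#' @param feature_set Extractor name (restricts candidates to one
#'   extraction setting) or `"all"` (pool every extractor's features).
#' @param ccc_threshold Reproducibility threshold on the generalized CCC.
#' @param n_features Number of features handed to the Cox model (mRMR
#'   target); fewer are used when fewer survive the filters.
#' @param folds,repeats Cross-validation shape.
#' @param c_min,p_max Univariate filter parameters.
#' @param seed Base seed; repetition r uses `seed + r`.
#' @return A `cv_config` list.
#' @export
cv_config <- function(feature_set = "all", ccc_threshold = 0, n_features = 4,
                      folds = 10, repeats = 100, c_min = 0.55, p_max = 0.1,
                      seed = 1) {
  structure(list(feature_set = feature_set, ccc_threshold = ccc_threshold,
                 n_features = as.integer(n_features), folds = as.integer(folds),
                 repeats = as.integer(repeats), c_min = c_min, p_max = p_max,
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' The default experiment grid enumeration
#'
#' 9 feature sets (8 extractor settings plus `"all"`) x 5 CCC thresholds
#' (0, 0.8, 0.85, 0.9, 0.95) x 7 feature counts (1, 2, 4, 8, 16, 32, 64)
#' = 315 configurations.
#'
#' @param feature_sets,thresholds,counts Optional overrides.
#' @return data.frame with columns `feature_set`, `ccc_threshold`,
#'   `n_features`.
#' @export
cv_grid_configs <- function(feature_sets = c(extractor_settings()$name, "all"),
                            thresholds = c(0, 0.8, 0.85, 0.9, 0.95),
                            counts = c(1, 2, 4, 8, 16, 32, 64)) {
  g <- expand.grid(feature_set = feature_sets, ccc_threshold = thresholds,
                   n_features = counts, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g[order(g$feature_set, g$ccc_threshold, g$n_features), , drop = FALSE]
}

# event-stratified fold assignment (shuffled within strata)
stratified_folds <- function(event, k) {
  fold <- integer(length(event))
  for (lev in unique(event)) {
    idx <- sample(which(event == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated cross-validation of the full modelling procedure
#'
#' Per repetition: an event-stratified shuffled k-fold split; within each
#' training fold only — standardization, orientation, the CCC / C-index /
#' Cox-p filters, mRMR selection and the multivariable Cox fit; the test
#' fold is scored with the training fold's scaling, orientation and
#' coefficients, and evaluated by Harrell's C. A repetition's value is the
#' mean over its folds; the summary is the mean over repetitions with a
#' 2.5/97.5 percentile interval. Folds in which no candidate survives the
#' filters are skipped and counted.
#'
#' @param cohort A `survival_cohort`.
#' @param ccc_table Reproducibility table (e.g. [generalized_ccc_table()]
#'   output) with columns `feature`, `roi`, `extractor`, `ccc`; matched to
#'   cohort features by the (roi, extractor, feature) id.
#' @param config A [cv_config()].
#' @return A `cv_result`: `config`, per-repetition C-indexes `rep_cindex`,
#'   `c_mean`, `ci` (2.5/97.5 percentiles), `selection_freq` (data.frame id
#'   / freq), `prop_liver` (mean fraction of selected features from the
#'   parenchyma ROI), `mean_available` (mean candidate count after
#'   filtering), `n_skipped_folds`, `n_failed_folds`.
#' @export
repeated_cv <- function(cohort, ccc_table, config) {
  stopifnot(inherits(cohort, "survival_cohort"), inherits(config, "cv_config"))
  info <- cohort$feature_info
  keep <- if (identical(config$feature_set, "all")) rep(TRUE, nrow(info))
          else info$extractor == config$feature_set
  if (!any(keep)) abort("no features for feature set '%s'", config$feature_set)
  X_all <- cohort$features[, info$id[keep], drop = FALSE]
  info <- info[keep, , drop = FALSE]
  ccc_lookup <- if (!is.null(ccc_table)) {
    stats::setNames(ccc_table$ccc,
                    make_feature_id(ccc_table$roi, ccc_table$extractor, ccc_table$feature))
  } else NULL
  time <- cohort$subjects$time_months
  event <- cohort$subjects$event
  if (sum(event) < config$folds)
    warning("fewer events than folds; fold fits may be unstable")
  sel_count <- stats::setNames(numeric(ncol(X_all)), colnames(X_all))
  rep_c <- numeric(config$repeats)
  prop_liver_num <- 0; prop_liver_den <- 0
  avail_sum <- 0; avail_n <- 0
  n_skipped <- 0L; n_failed <- 0L
  n_models <- 0L
  for (r in seq_len(config$repeats)) {
    fold_c <- rep(NA_real_, config$folds)
    with_seed(config$seed + r, {
      fold <- stratified_folds(event, config$folds)
      for (f in seq_len(config$folds)) {
        tr <- fold != f; te <- !tr
        Xtr <- X_all[tr, , drop = FALSE]
        mu <- colMeans(Xtr); sdv <- apply(Xtr, 2, stats::sd)
        usable <- is.finite(sdv) & sdv > 0
        Xtr <- scale(Xtr[, usable, drop = FALSE], center = mu[usable], scale = sdv[usable])
        flt <- filter_features(Xtr, time[tr], event[tr], ccc_lookup,
                               config$ccc_threshold, config$c_min, config$p_max)
        avail_sum <- avail_sum + length(flt$features); avail_n <- avail_n + 1
        if (length(flt$features) == 0) { n_skipped <- n_skipped + 1L; next }
        Xcand <- sweep(Xtr[, flt$features, drop = FALSE], 2, flt$sign, "*")
        sel <- mrmr_select(Xcand, flt$cindex - 0.5, config$n_features)
        model <- tryCatch(fit_cox(Xcand[, sel, drop = FALSE], time[tr], event[tr]),
                          error = function(e) NULL)
        if (is.null(model)) { n_failed <- n_failed + 1L; next }
        n_models <- n_models + 1L
        sel_count[sel] <- sel_count[sel] + 1
        sel_roi <- info$roi[match(sel, info$id)]
        prop_liver_num <- prop_liver_num + mean(sel_roi == "parenchyma")
        prop_liver_den <- prop_liver_den + 1
        Xte <- scale(X_all[te, flt$features, drop = FALSE],
                     center = mu[flt$features], scale = sdv[flt$features])
        Xte <- sweep(Xte, 2, flt$sign, "*")
        risk <- risk_score(model, Xte)
        fold_c[f] <- harrell_cindex(risk, time[te], event[te])
      }
    })
    rep_c[r] <- mean(fold_c, na.rm = TRUE)
  }
  valid <- is.finite(rep_c)
  structure(list(
    config = config,
    rep_cindex = rep_c,
    c_mean = if (any(valid)) mean(rep_c[valid]) else NA_real_,
    ci = if (any(valid)) stats::quantile(rep_c[valid], c(0.025, 0.975), names = FALSE)
         else c(NA_real_, NA_real_),
    selection_freq = data.frame(id = names(sel_count),
                                freq = if (n_models > 0) unname(sel_count) / n_models
                                       else unname(sel_count),
                                stringsAsFactors = FALSE),
    prop_liver = if (prop_liver_den > 0) prop_liver_num / prop_liver_den else NA_real_,
    mean_available = if (avail_n > 0) avail_sum / avail_n else NA_real_,
    n_skipped_folds = n_skipped,
    n_failed_folds = n_failed,
    n_models = n_models), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s / CCC>=%.2f / k=%d: C = %.3f (%.3f-%.3f), %d models, %d empty folds\n",
              x$config$feature_set, x$config$ccc_threshold, x$config$n_features,
              x$c_mean, x$ci[1], x$ci[2], x$n_models, x$n_skipped_folds))
  invisible(x)
}

#' Run the full cross-validation experiment grid
#'
#' Enumerates every (feature set, CCC threshold, feature count)
#' configuration, runs [repeated_cv()] for each, and returns a tidy results
#' table. Per-cell failures are recorded, never propagated.
#'
#' @param cohort A `survival_cohort`.
#' @param ccc_table Reproducibility table (see [repeated_cv()]).
#' @param grid Configuration grid (default [cv_grid_configs()]).
#' @param folds,repeats,seed,c_min,p_max Shared settings for every cell.
#' @return List with `results` (one row per cell: `feature_set`,
#'   `ccc_threshold`, `n_features`, `c_mean`, `ci_lo`, `ci_hi`,
#'   `prop_liver`, `mean_available`, `n_skipped_folds`, `status`) and
#'   `selection` (long selection-frequency table).
#' @export
experiment_grid <- function(cohort, ccc_table, grid = cv_grid_configs(),
                            folds = 10, repeats = 100, seed = 1,
                            c_min = 0.55, p_max = 0.1) {
  res <- vector("list", nrow(grid))
  selrows <- list()
  for (g in seq_len(nrow(grid))) {
    cfg <- cv_config(feature_set = grid$feature_set[g],
                     ccc_threshold = grid$ccc_threshold[g],
                     n_features = grid$n_features[g],
                     folds = folds, repeats = repeats,
                     c_min = c_min, p_max = p_max, seed = seed)
    cell <- tryCatch(repeated_cv(cohort, ccc_table, cfg), error = function(e) e)
    if (inherits(cell, "error")) {
      res[[g]] <- data.frame(feature_set = cfg$feature_set,
                             ccc_threshold = cfg$ccc_threshold,
                             n_features = cfg$n_features,
                             c_mean = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                             prop_liver = NA_real_, mean_available = NA_real_,
                             n_skipped_folds = NA_integer_,
                             status = paste("error:", conditionMessage(cell)),
                             stringsAsFactors = FALSE)
    } else {
      res[[g]] <- data.frame(feature_set = cfg$feature_set,
                             ccc_threshold = cfg$ccc_threshold,
                             n_features = cfg$n_features,
                             c_mean = cell$c_mean, ci_lo = cell$ci[1], ci_hi = cell$ci[2],
                             prop_liver = cell$prop_liver,
                             mean_available = cell$mean_available,
                             n_skipped_folds = cell$n_skipped_folds,
                             status = if (cell$n_models == 0) "empty" else "ok",
                             stringsAsFactors = FALSE)
      sf <- cell$selection_freq[cell$selection_freq$freq > 0, , drop = FALSE]
      if (nrow(sf) > 0) {
        sf$feature_set <- cfg$feature_set
        sf$ccc_threshold <- cfg$ccc_threshold
        sf$n_features <- cfg$n_features
        selrows[[length(selrows) + 1L]] <- sf
      }
    }
  }
  list(results = do.call(rbind, res),
       selection = if (length(selrows)) do.call(rbind, selrows) else
         data.frame(id = character(0), freq = numeric(0)))
}
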