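# First-order features, texture aggregation (2.5D / 3D), and the full
# per-setting extraction driver.

#' First-order (histogram) features
#'
#' The 18 default first-order features. Entropy and Uniformity are computed
#' on the discretized gray levels; all other statistics on the raw HU values
#' of the retained voxels. Percentiles use linear interpolation (R type 7).
#' Skewness is the population third standardized moment and Kurtosis the
#' non-excess fourth; both are 0 for a constant ROI. Independent of the
#' texture aggregation mode.
#'
#' @param image An [image_volume()] (used for voxel volume via spacing; raw
#'   values come from the discretized ROI).
#' @param roi A [discretize()]d ROI.
#' @return Named numeric vector of 18 features (`firstorder_*`).
#' @export
first_order_features <- function(image, roi) {
  stopifnot(inherits(roi, "discretized_roi"))
  x <- roi$raw
  if (length(x) == 0) abort("empty ROI")
  n <- length(x)
  vox <- prod(roi$spacing)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  lv <- roi$levels[!is.na(roi$levels)]
  p <- tabulate(lv, roi$n_bins) / n
  robust <- x[x >= q[1] & x <= q[5]]
  out <- c(
    Energy = sum(x^2),
    TotalEnergy = vox * sum(x^2),
    Entropy = -sum(xlog2(p)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(x),
    Mean = m,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - m)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((x - m)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2)
  )
  names(out) <- paste0("firstorder_", names(out))
  out
}

#' Aggregate texture features over directions / neighborhoods
#'
#' Directional classes (GLCM, GLRLM): one matrix per direction — in 2.5D a
#' single matrix per in-plane direction pooling voxel pairs from all slices,
#' in 3D one matrix per each of the 13 unique directions — features computed
#' per direction and averaged. Non-directional classes (GLSZM, GLDM, NGTDM):
#' a single matrix, with in-plane (8-connected) neighborhoods in 2.5D and
#' 26-connected neighborhoods in 3D. Directions whose matrix is empty (no
#' valid pairs) are excluded from the average; if none is valid the features
#' are returned as NA.
#'
#' @param roi A [discretize()]d ROI.
#' @param class Texture class name.
#' @param aggregation `"2.5D"` or `"3D"`.
#' @return Named numeric vector of the class's features.
#' @export
aggregate_texture <- function(roi, class = c("glcm", "glrlm", "glszm", "gldm", "ngtdm"),
                              aggregation = c("2.5D", "3D")) {
  class <- match.arg(class)
  aggregation <- match.arg(aggregation)
  n_vox <- sum(!is.na(roi$levels))
  if (class %in% c("glcm", "glrlm")) {
    dirs <- if (aggregation == "2.5D") directions_2d() else directions_3d()
    per_dir <- lapply(dirs, function(d) {
      P <- build_texture_matrix(roi, class, direction = d)
      if (sum(P) == 0 && class == "glcm") return(NULL)  # no valid pairs
      if (class == "glcm") glcm_features(P) else glrlm_features(P, n_vox)
    })
    per_dir <- Filter(Negate(is.null), per_dir)
    if (length(per_dir) == 0) {
      nm <- paste0(class, "_", feature_registry_names(class))
      return(stats::setNames(rep(NA_real_, length(nm)), nm))
    }
    mat <- do.call(rbind, per_dir)
    colMeans(mat)  # NA propagates if undefined in any direction
  } else {
    M <- build_texture_matrix(roi, class, mode = aggregation)
    switch(class,
           glszm = glszm_features(M, n_vox),
           gldm = gldm_features(M, n_vox),
           ngtdm = ngtdm_features(M))
  }
}

#' Extract all 93 features for one image/ROI under one extractor setting
#'
#' Pipeline: resample (cubic-spline image, nearest-neighbor mask) to the
#' setting's grid, resegment to the HU window, discretize to `n_bins`
#' levels, then compute the 18 first-order and 75 texture features with the
#' setting's aggregation mode.
#'
#' @param image An [image_volume()].
#' @param mask An [roi_mask()] aligned to `image`.
#' @param setting Extractor setting name or row (see [extractor_settings()]).
#' @param n_bins Discretization level count.
#' @param window Resegmentation HU window.
#' @return Named numeric vector of 93 features.
#' @export
extract_features <- function(image, mask, setting, n_bins = 24,
                             window = c(-50, 350)) {
  setting <- resolve_setting(setting)
  rp <- resample_pair(image, mask, setting)
  mk <- resegment(rp$image, rp$mask, window)
  droi <- discretize(rp$image, mk, n_bins)
  agg <- setting$aggregation
  c(first_order_features(rp$image, droi),
    aggregate_texture(droi, "glcm", agg),
    aggregate_texture(droi, "glrlm", agg),
    aggregate_texture(droi, "glszm", agg),
    aggregate_texture(droi, "gldm", agg),
    aggregate_texture(droi, "ngtdm", agg))
}

#' Extract features for every ROI and extractor setting
#'
#' @param image An [image_volume()].
#' @param masks Named list of [roi_mask()]s (names = ROI roles).
#' @param settings Character vector of setting names, or a data.frame of
#'   setting rows; default all eight.
#' @param n_bins,window Passed to [extract_features()].
#' @param subject_id Optional subject tag attached to error messages.
#' @return Long data.frame with columns `roi`, `extractor`, `feature`,
#'   `value` (93 rows per ROI x setting).
#' @export
extract_all <- function(image, masks, settings = extractor_settings()$name,
                        n_bins = 24, window = c(-50, 350), subject_id = NULL) {
  if (is.data.frame(settings)) settings <- settings$name
  if (length(settings) == 0) abort("settings must be nonempty")
  if (is.null(names(masks)))
    names(masks) <- vapply(masks, function(m) m$role, "")
  rows <- list()
  for (roi_name in names(masks)) {
    for (sname in settings) {
      fv <- tryCatch(
        extract_features(image, masks[[roi_name]], sname, n_bins, window),
        error = function(e) abort("extraction failed (subject=%s, setting=%s, ROI=%s): %s",
                                  subject_id %||% "?", sname, roi_name, conditionMessage(e)))
      rows[[length(rows) + 1L]] <- data.frame(
        roi = roi_name, extractor = sname, feature = names(fv),
        value = unname(fv), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
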