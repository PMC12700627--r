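# Preprocessing: grid resampling, HU-window resegmentation, fixed-bin-count
# discretization.
#
# Resampling convention: the output grid starts at the input physical extent
# (voxel centres at origin + (i-1)*spacing; the extent covers the input
# bounding box, with the first output centre shifted by half the spacing
# difference). Images are interpolated with separable natural cubic splines,
# which reproduce linear intensity ramps exactly; samples outside the input
# support are clamped to the nearest edge. Masks use nearest-neighbor.

new_axis_grid <- function(n, sp, o, sp_new) {
  n_new <- max(1L, as.integer(ceiling(n * sp / sp_new - 1e-9)))
  o_new <- o - sp / 2 + sp_new / 2
  list(n = n_new, sp = sp_new, o = o_new)
}

# resample one axis of a 3D array onto new physical coordinates
resample_axis <- function(arr, axis, old_x, new_x, method = c("spline", "nearest")) {
  method <- match.arg(method)
  d <- dim(arr)
  if (length(old_x) == d[axis] && length(new_x) == length(old_x) &&
      max(abs(old_x - new_x)) < 1e-9) return(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  xq <- pmin(max(old_x), pmax(min(old_x), new_x))  # edge clamp
  if (method == "nearest") {
    idx <- vapply(xq, function(x) which.min(abs(old_x - x)), integer(1))
    out <- m[idx, , drop = FALSE]
  } else if (length(old_x) < 2L) {
    out <- m[rep(1L, length(xq)), , drop = FALSE]
  } else {
    out <- vapply(seq_len(ncol(m)), function(j) {
      stats::splinefun(old_x, m[, j], method = "natural")(xq)
    }, numeric(length(xq)))
    if (!is.matrix(out)) out <- matrix(out, nrow = length(xq))
  }
  nd <- d[perm]; nd[1] <- length(xq)
  aperm(array(out, nd), order(perm))
}

resample_grid <- function(x, target_spacing, method) {
  vals <- x$values
  sp_new <- target_spacing; org_new <- x$origin
  for (ax in 1:3) {
    if (is.na(target_spacing[ax])) { sp_new[ax] <- x$spacing[ax]; next }
    g <- new_axis_grid(dim(vals)[ax], x$spacing[ax], x$origin[ax], target_spacing[ax])
    old_x <- axis_coords(dim(vals)[ax], x$spacing[ax], x$origin[ax])
    new_x <- axis_coords(g$n, g$sp, g$o)
    vals <- resample_axis(vals, ax, old_x, new_x, method)
    sp_new[ax] <- g$sp; org_new[ax] <- g$o
  }
  list(values = vals, spacing = sp_new, origin = org_new)
}

#' Resample an image and its mask to an extractor setting's grid
#'
#' The image is interpolated with cubic splines and the mask with
#' nearest-neighbor onto the same target grid. A setting with `z_mm = NA`
#' (the "i" settings) leaves the z axis untouched.
#'
#' @param image An [image_volume()].
#' @param mask An [roi_mask()] aligned to `image`.
#' @param setting One row of [extractor_settings()] (or a name from it).
#' @return List with resampled `image` and `mask`.
#' @export
resample_pair <- function(image, mask, setting) {
  setting <- resolve_setting(setting)
  stopifnot(inherits(image, "image_volume"), inherits(mask, "roi_mask"))
  if (!all(dim(image$values) == dim(mask$values)))
    abort("mask grid %s does not match image grid %s",
          paste(dim(mask$values), collapse = "x"),
          paste(dim(image$values), collapse = "x"))
  target <- c(setting$inplane_mm, setting$inplane_mm, setting$z_mm)
  ri <- resample_grid(image, target, "spline")
  rm_ <- resample_grid(list(values = array(as.numeric(mask$values), dim(mask$values)),
                            spacing = mask$spacing, origin = mask$origin),
                       target, "nearest")
  mvals <- rm_$values > 0.5
  if (!any(mvals))
    abort("mask '%s' is empty after resampling for setting %s", mask$role, setting$name)
  list(image = image_volume(ri$values, ri$spacing, ri$origin),
       mask = roi_mask(mvals, rm_$spacing, rm_$origin, role = mask$role))
}

resolve_setting <- function(setting) {
  if (is.character(setting) && length(setting) == 1L) {
    st <- extractor_settings()
    row <- st[st$name == setting, ]
    if (nrow(row) != 1L) abort("unknown extractor setting '%s'", setting)
    return(as.list(row))
  }
  setting <- as.list(setting)
  stopifnot(all(c("name", "inplane_mm", "z_mm", "aggregation") %in% names(setting)))
  setting
}

#' Resegment an ROI by an intensity window
#'
#' Retains exactly the mask voxels whose intensity lies in the closed
#' interval `[window[1], window[2]]`, the usual guard against metal
#' artifacts and implausible outlier HU values.
#'
#' @param image An [image_volume()].
#' @param mask An [roi_mask()] on the same grid.
#' @param window Length-2 numeric, `lo <= hi` (HU).
#' @return The resegmented [roi_mask()].
#' @export
resegment <- function(image, mask, window = c(-50, 350)) {
  stopifnot(inherits(image, "image_volume"), inherits(mask, "roi_mask"))
  if (length(window) != 2L || window[1] > window[2])
    abort("window must be c(lo, hi) with lo <= hi")
  if (!any(mask$values)) abort("mask '%s' is empty", mask$role)
  keep <- mask$values & image$values >= window[1] & image$values <= window[2]
  if (!any(keep))
    abort("ROI '%s' empty after resegmentation to [%g, %g] HU",
          mask$role, window[1], window[2])
  roi_mask(keep, mask$spacing, mask$origin, role = mask$role)
}

#' Discretize ROI intensities to a fixed number of bins
#'
#' Fixed-bin-count scheme: `n_bins` uniform bins over the `[min, max]` range
#' of the retained ROI intensities; level = `1 + floor(n_bins * (x - min) /
#' (max - min))` with the maximum assigned level `n_bins`. A constant ROI
#' maps entirely to level 1. Empty bins keep their index (gray levels are
#' not re-compacted).
#'
#' @param image An [image_volume()].
#' @param mask A (resegmented) [roi_mask()].
#' @param n_bins Number of gray levels (>= 2).
#' @return A `discretized_roi`: list with `levels` (integer array, `NA`
#'   outside the ROI), `mask`, `n_bins`, `bin_edges`, `raw` (HU values of
#'   retained voxels), `spacing`.
#' @export
discretize <- function(image, mask, n_bins = 24) {
  stopifnot(inherits(image, "image_volume"), inherits(mask, "roi_mask"))
  if (n_bins < 2) abort("n_bins must be >= 2")
  if (!any(mask$values)) abort("mask '%s' is empty", mask$role)
  x <- image$values[mask$values]
  lo <- min(x); hi <- max(x)
  lv_arr <- array(NA_integer_, dim(image$values))
  if (hi == lo) {
    lv <- rep(1L, length(x))
    edges <- seq(lo, lo + n_bins, length.out = n_bins + 1)
  } else {
    lv <- pmin(n_bins, 1L + floor(n_bins * (x - lo) / (hi - lo)))
    edges <- seq(lo, hi, length.out = n_bins + 1)
  }
  lv_arr[mask$values] <- as.integer(lv)
  # crop to the ROI bounding box: voxels outside the ROI never contribute
  # to any matrix, and smaller arrays make the builders cheaper
  bb <- lapply(1:3, function(ax) {
    pr <- apply(mask$values, ax, any)
    range(which(pr))
  })
  lv_arr <- lv_arr[bb[[1]][1]:bb[[1]][2], bb[[2]][1]:bb[[2]][2],
                   bb[[3]][1]:bb[[3]][2], drop = FALSE]
  structure(list(levels = lv_arr, mask = mask$values, n_bins = as.integer(n_bins),
                 bin_edges = edges, raw = x, spacing = mask$spacing,
                 role = mask$role),
            class = "discretized_roi")
}

#' @export
print.discretized_roi <- function(x, ...) {
  cat(sprintf("<discretized_roi:%s> %d voxels, %d bins, HU [%.1f, %.1f]\n",
              x$role, length(x$raw), x$n_bins, min(x$raw), max(x$raw)))
  invisible(x)
}
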