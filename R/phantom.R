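# Synthetic phantom generation and reconstruction-variant emulation.
#
# The phantom emulates the geometry the real study works with: a textured
# "liver" background containing a hypodense ellipsoidal tumor, imaged at a
# thin base slice spacing and then re-"reconstructed" at coarser slice
# thicknesses and different denoising (ASiR-like) levels.

THICKNESS_GRID <- c(2.5, 3.75, 5)
ASIR_GRID <- seq(0, 60, by = 10)

#' Phantom specification
#'
#' Defines a synthetic 3D phantom: a stationary correlated Gaussian texture
#' field in HU on a thin-spacing grid, with an ellipsoidal tumor ROI offset
#' in mean HU from a surrounding shell of parenchyma.
#'
#' @param grid_shape Voxels per axis (x, y, z).
#' @param thin_spacing_mm Base voxel spacing (mm); the z spacing must divide
#'   the reconstruction slice thicknesses (2.5, 3.75, 5 mm), e.g. 1.25 mm.
#' @param mean_hu Marginal mean of the background/parenchyma texture (HU).
#' @param sd_hu Marginal standard deviation of the texture (HU).
#' @param corr_length_mm Correlation length of the texture per axis (mm);
#'   0 gives white noise.
#' @param tumor_contrast_hu Mean HU offset of the tumor relative to the
#'   parenchyma (negative = hypodense, typical of liver metastases in
#'   portal-venous CT).
#' @param tumor_center_mm Tumor centre (mm); default grid centre.
#' @param tumor_radii_mm Ellipsoid radii of the tumor (mm).
#' @param shell_radii_mm Outer ellipsoid radii of the parenchyma shell (mm).
#' @param gap_mm Margin between tumor and parenchyma masks (mm), keeping the
#'   ROIs disjoint.
#' @param seed RNG seed; phantom generation is a pure function of the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 16),
                         thin_spacing_mm = c(1.25, 1.25, 1.25),
                         mean_hu = 100, sd_hu = 20,
                         corr_length_mm = c(2.5, 2.5, 2.5),
                         tumor_contrast_hu = -40,
                         tumor_center_mm = NULL,
                         tumor_radii_mm = c(8, 8, 7),
                         shell_radii_mm = c(17, 17, 8.5),
                         gap_mm = 2,
                         seed = 1) {
  thin_spacing_mm <- as.numeric(thin_spacing_mm)
  if (length(thin_spacing_mm) == 1L) thin_spacing_mm <- rep(thin_spacing_mm, 3)
  if (any(thin_spacing_mm <= 0)) abort("spacings must be positive")
  grid_shape <- as.integer(grid_shape)
  if (is.null(tumor_center_mm))
    tumor_center_mm <- (grid_shape - 1) * thin_spacing_mm / 2
  spec <- list(grid_shape = grid_shape, thin_spacing_mm = thin_spacing_mm,
               mean_hu = mean_hu, sd_hu = sd_hu,
               corr_length_mm = rep(as.numeric(corr_length_mm), length.out = 3),
               tumor_contrast_hu = tumor_contrast_hu,
               tumor_center_mm = as.numeric(tumor_center_mm),
               tumor_radii_mm = rep(as.numeric(tumor_radii_mm), length.out = 3),
               shell_radii_mm = rep(as.numeric(shell_radii_mm), length.out = 3),
               gap_mm = gap_mm, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

# separable Gaussian smoothing of a 3D array along one axis (reflected edges)
smooth_axis <- function(arr, axis, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  hw <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-0.5 * ((-hw:hw) / sigma_vox)^2)
  k <- k / sum(k)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  n <- nrow(m)
  pad_idx <- c(rev(seq_len(min(hw, n))), seq_len(n),
               rev(n + 1 - seq_len(min(hw, n))))
  # if hw > n the reflection above is short; recycle clamp
  if (hw > n) pad_idx <- c(rep(1L, hw - n), pad_idx, rep(n, hw - n))
  mp <- m[pad_idx, , drop = FALSE]
  sm <- apply(mp, 2, function(col) stats::filter(col, k, sides = 2))
  sm <- sm[(hw + 1):(hw + n), , drop = FALSE]
  out <- array(sm, d[perm])
  aperm(out, order(perm))
}

ellipsoid_mask <- function(grid_shape, spacing, center, radii) {
  cx <- axis_coords(grid_shape[1], spacing[1], 0)
  cy <- axis_coords(grid_shape[2], spacing[2], 0)
  cz <- axis_coords(grid_shape[3], spacing[3], 0)
  dx2 <- ((cx - center[1]) / radii[1])^2
  dy2 <- ((cy - center[2]) / radii[2])^2
  dz2 <- ((cz - center[3]) / radii[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

#' Generate a phantom image with tumor and parenchyma ROI masks
#'
#' The texture is a stationary Gaussian random field built by separable
#' Gaussian smoothing of white noise, rescaled to the requested marginal SD,
#' with the tumor region shifted by the configured HU contrast. Deterministic
#' given the spec (including its seed).
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `image` ([image_volume()]), `tumor` and
#'   `parenchyma` ([roi_mask()]s on the same grid).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape; sp <- spec$thin_spacing_mm
  tumor <- ellipsoid_mask(gs, sp, spec$tumor_center_mm, spec$tumor_radii_mm)
  shell_outer <- ellipsoid_mask(gs, sp, spec$tumor_center_mm, spec$shell_radii_mm)
  tumor_margin <- ellipsoid_mask(gs, sp, spec$tumor_center_mm,
                                 spec$tumor_radii_mm + spec$gap_mm)
  paren <- shell_outer & !tumor_margin
  if (sum(tumor) < 64) abort("tumor ROI degenerate: only %d voxels after voxelization", sum(tumor))
  if (sum(paren) < 64) abort("parenchyma ROI degenerate: only %d voxels after voxelization", sum(paren))
  vals <- with_seed(spec$seed, {
    field <- array(stats::rnorm(prod(gs)), gs)
    for (ax in 1:3) {
      sig <- spec$corr_length_mm[ax] / sp[ax]
      field <- smooth_axis(field, ax, sig)
    }
    if (spec$sd_hu > 0) {
      fsd <- stats::sd(as.numeric(field))
      field <- field / fsd * spec$sd_hu
    } else {
      field <- array(0, gs)
    }
    v <- spec$mean_hu + field
    v[tumor] <- v[tumor] + spec$tumor_contrast_hu
    v
  })
  list(image = image_volume(vals, sp),
       tumor = roi_mask(tumor, sp, role = "tumor"),
       parenchyma = roi_mask(paren, sp, role = "parenchyma"))
}

#' Reconstruction key
#'
#' Identifies one reconstruction variant of a subject's scan: one of three
#' slice thicknesses (2.5, 3.75, 5 mm) and seven ASiR-like denoising levels
#' (0 to 60 percent).
#'
#' @param subject_id Subject identifier string.
#' @param slice_thickness_mm One of 2.5, 3.75, 5.
#' @param asir_percent One of 0, 10, ..., 60.
#' @return A `reconstruction_key` list.
#' @export
reconstruction_key <- function(subject_id, slice_thickness_mm, asir_percent) {
  if (!slice_thickness_mm %in% THICKNESS_GRID)
    abort("slice_thickness_mm must be one of %s", paste(THICKNESS_GRID, collapse = ", "))
  if (!asir_percent %in% ASIR_GRID)
    abort("asir_percent must be one of %s", paste(ASIR_GRID, collapse = ", "))
  structure(list(subject_id = as.character(subject_id),
                 slice_thickness_mm = slice_thickness_mm,
                 asir_percent = asir_percent),
            class = "reconstruction_key")
}

#' The full reconstruction grid
#'
#' @return A 21-row data.frame of every slice-thickness / ASiR combination.
#' @export
reconstruction_grid <- function() {
  expand.grid(slice_thickness_mm = THICKNESS_GRID,
              asir_percent = ASIR_GRID,
              KEEP.OUT.ATTRS = FALSE)
}

# deterministic per-key noise seed so reconstruction is reproducible
key_seed <- function(key) {
  h <- sum(utf8ToInt(key$subject_id) * seq_along(utf8ToInt(key$subject_id)))
  as.integer((h * 7919 + key$slice_thickness_mm * 1000 + key$asir_percent * 17) %% .Machine$integer.max)
}

#' Emulate a reconstruction variant of a thin-slice volume
#'
#' Thicker slices are formed by averaging contiguous, non-overlapping blocks
#' of thin slices; reconstruction noise is emulated as additive zero-mean
#' Gaussian noise whose SD shrinks linearly with the ASiR-like level
#' (multiplier `1 - 0.5 * asir/60`) and with the square root of the slice
#' averaging factor. This emulates the qualitative role of slice thickness
#' and iterative-reconstruction strength only; it is not CT reconstruction.
#'
#' @param volume Thin-spacing [image_volume()].
#' @param key A [reconstruction_key()].
#' @param noise_sd_hu Base noise SD (HU) at ASiR 0 and thin spacing; 0
#'   disables noise.
#' @param seed Noise seed; default derived deterministically from the key.
#' @return An [image_volume()] with z spacing equal to the slice thickness.
#' @export
reconstruct <- function(volume, key, noise_sd_hu = 10, seed = NULL) {
  stopifnot(inherits(volume, "image_volume"), inherits(key, "reconstruction_key"))
  ratio <- key$slice_thickness_mm / volume$spacing[3]
  if (abs(ratio - round(ratio)) > 1e-6)
    abort("slice thickness %.2f is not an integer multiple of thin z-spacing %.3f",
          key$slice_thickness_mm, volume$spacing[3])
  r <- as.integer(round(ratio))
  d <- dim(volume$values)
  nz <- d[3] %/% r
  if (nz < 1) abort("volume too thin for %.2f mm slices", key$slice_thickness_mm)
  v <- volume$values[, , seq_len(nz * r), drop = FALSE]
  dim(v) <- c(d[1], d[2], r, nz)
  thick <- apply(v, c(1, 2, 4), mean)
  sd_noise <- noise_sd_hu * (1 - 0.5 * key$asir_percent / 60) / sqrt(r)
  if (sd_noise > 0) {
    if (is.null(seed)) seed <- key_seed(key)
    thick <- thick + with_seed(seed, array(stats::rnorm(length(thick), sd = sd_noise), dim(thick)))
  }
  sp <- c(volume$spacing[1:2], key$slice_thickness_mm)
  # origin of first thick-slice centre sits mid-way through its thin block
  org <- volume$origin
  org[3] <- org[3] - volume$spacing[3] / 2 + key$slice_thickness_mm / 2
  image_volume(thick, sp, org)
}

#' Resample a reference ROI mask to a new slice spacing
#'
#' Nearest-neighbor relabelling of the reference mask onto a grid with the
#' target z spacing (in-plane grid unchanged), as done when propagating a
#' reference segmentation to reconstructions with other slice thicknesses.
#'
#' @param mask An [roi_mask()] on the reference grid.
#' @param target_zspacing_mm Target slice spacing (mm).
#' @return An [roi_mask()] on the target grid.
#' @export
resample_reference_mask <- function(mask, target_zspacing_mm) {
  stopifnot(inherits(mask, "roi_mask"))
  if (!any(mask$values)) abort("reference mask is empty")
  d <- dim(mask$values)
  spz <- mask$spacing[3]
  nz_new <- max(1L, floor(d[3] * spz / target_zspacing_mm))
  oz_new <- mask$origin[3] - spz / 2 + target_zspacing_mm / 2
  newc <- axis_coords(nz_new, target_zspacing_mm, oz_new)
  oldc <- axis_coords(d[3], spz, mask$origin[3])
  idx <- vapply(newc, function(z) which.min(abs(oldc - z)), integer(1))
  out <- mask$values[, , idx, drop = FALSE]
  if (!any(out)) abort("mask '%s' empty after resampling to %.2f mm", mask$role, target_zspacing_mm)
  roi_mask(out, c(mask$spacing[1:2], target_zspacing_mm),
           c(mask$origin[1:2], oz_new), role = mask$role)
}
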