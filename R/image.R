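# Image and mask containers plus NIfTI I/O.
#
# Arrays are stored in (x, y, z) order with z the slice axis; `spacing` is
# the physical voxel size in mm and `origin` the world coordinate of the
# centre of voxel (1, 1, 1).

#' Construct an image volume
#'
#' @param values 3D numeric array of intensities (HU for CT-like images).
#' @param spacing Voxel spacing in mm, length 3 `(x, y, z)` (scalar recycled).
#' @param origin World coordinate (mm) of the first voxel centre.
#' @return An `image_volume` object (list with `values`, `spacing`, `origin`).
#' @export
image_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    abort("image values must be a 3D array, got %d dims",
          length(dim(values) %||% dim(as.array(values))))
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("spacing must be 3 positive finite values")
  if (any(!is.finite(values)))
    abort("image contains non-finite values")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' Construct an ROI mask
#'
#' @param values 3D logical (or 0/1) array aligned to an image grid.
#' @param spacing Voxel spacing in mm.
#' @param origin World coordinate of the first voxel centre.
#' @param role ROI role, `"tumor"` or `"parenchyma"`.
#' @return An `roi_mask` object.
#' @export
roi_mask <- function(values, spacing, origin = c(0, 0, 0),
                     role = c("tumor", "parenchyma")) {
  role <- match.arg(role)
  if (!is.array(values) || length(dim(values)) != 3L)
    abort("mask values must be a 3D array")
  values <- array(as.logical(values), dim(values))
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) abort("spacing must be positive")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin), role = role),
            class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask:%s> %s voxels, %d in ROI, spacing %s mm\n",
              x$role, paste(dim(x$values), collapse = "x"),
              sum(x$values),
              paste(format(x$spacing, trim = TRUE), collapse = "x")))
  invisible(x)
}

#' Read a NIfTI file as an image volume or ROI mask
#'
#' Spacing is taken from the header `pixdim`; the origin from the stored
#' affine. Mask files are binarized at 0.5.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param mask Read as a binary ROI mask rather than an intensity image.
#' @param role ROI role when `mask = TRUE`.
#' @return An [image_volume()] or [roi_mask()].
#' @export
read_nifti <- function(path, mask = FALSE, role = "tumor") {
  if (!file.exists(path)) abort("file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    abort("expected a 3D volume, got %d dimensions in %s", length(d), path)
  spacing <- abs(RNifti::pixdim(img))[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  vals <- array(as.numeric(img), d)
  if (mask) {
    roi_mask(vals > 0.5, spacing, origin, role = role)
  } else {
    image_volume(vals, spacing, origin)
  }
}

#' Write an image volume or ROI mask to NIfTI
#'
#' Intensities are stored as doubles so that write/read round trips are
#' exact; masks are stored as 8-bit integers.
#'
#' @param x An [image_volume()] or [roi_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  stopifnot(inherits(x, "image_volume") || inherits(x, "roi_mask"))
  vals <- if (inherits(x, "roi_mask")) array(as.integer(x$values), dim(x$values)) else x$values
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- x$spacing
  dtype <- if (inherits(x, "roi_mask")) "uint8" else "double"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

# voxel-centre world coordinates along one axis
axis_coords <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing
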