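# Gray-level matrix builders. All builders operate on a 3D integer array of
# discretized levels with NA outside the ROI, so that 2.5D variants fall out
# naturally by restricting neighbor offsets to the axial plane (dz = 0).

# unique direction offsets (up to sign): 4 in-plane, 13 in 3D
directions_2d <- function() list(c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L), c(-1L, 1L, 0L))

directions_3d <- function() {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  keep <- offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
    (offs$dz == 0 & offs$dy == 0 & offs$dx > 0)
  lapply(which(keep), function(i) as.integer(offs[i, ]))
}

# full neighbor sets (both signs): 8 in-plane, 26 in 3D
neighbors_full <- function(aggregation) {
  dirs <- if (aggregation == "2.5D") directions_2d() else directions_3d()
  c(dirs, lapply(dirs, function(d) -d))
}

# shift an array by offset d, padding with NA
shift_array <- function(a, d) {
  dm <- dim(a)
  out <- a
  out[] <- NA  # NA of the array's own type
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    s <- d[ax]
    if (s >= 0) { dst[[ax]] <- seq_len(dm[ax] - s); src[[ax]] <- seq_len(dm[ax] - s) + s }
    else { dst[[ax]] <- seq(1 - s, dm[ax]); src[[ax]] <- seq_len(dm[ax] + s) }
    if (abs(s) >= dm[ax]) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# all (level_from, level_to) pairs for offset d
level_pairs <- function(lv, d) {
  nb <- shift_array(lv, d)
  ok <- !is.na(lv) & !is.na(nb)
  cbind(lv[ok], nb[ok])
}

#' Build a gray-level texture matrix
#'
#' Low-level access to the five matrix builders. GLCM and GLRLM are
#' directional (pass a unit `direction` offset); GLSZM, GLDM and NGTDM take
#' a Chebyshev-distance-1 neighborhood (`mode` `"2.5D"` = 8 in-plane
#' neighbors, `"3D"` = 26 neighbors).
#'
#' @param roi A [discretize()]d ROI.
#' @param class One of `"glcm"`, `"glrlm"`, `"glszm"`, `"gldm"`, `"ngtdm"`.
#' @param direction Integer offset `(dx, dy, dz)` for directional classes.
#' @param mode `"2.5D"` or `"3D"` for the neighborhood classes.
#' @return For glcm: symmetric `n_bins x n_bins` count matrix. For glrlm:
#'   `n_bins x max_run_length` run count matrix. For glszm: `n_bins x
#'   max_zone_size` zone count matrix. For gldm: `n_bins x max_dependence`
#'   count matrix (dependence = 1 + equal-level neighbors; center counted).
#'   For ngtdm: list with level counts `n`, summed absolute differences `s`,
#'   probabilities `p` and `n_valid`.
#' @export
build_texture_matrix <- function(roi, class = c("glcm", "glrlm", "glszm", "gldm", "ngtdm"),
                                 direction = NULL, mode = c("3D", "2.5D")) {
  class <- match.arg(class)
  stopifnot(inherits(roi, "discretized_roi"))
  if (class %in% c("glcm", "glrlm")) {
    if (is.null(direction) || length(direction) != 3L)
      abort("%s requires a length-3 integer direction", class)
    direction <- as.integer(direction)
    if (all(direction == 0L) || any(abs(direction) > 1L))
      abort("direction must be a nonzero Chebyshev-1 offset")
    if (class == "glcm") return(glcm_matrix(roi$levels, direction, roi$n_bins))
    return(glrlm_matrix(roi$levels, direction, roi$n_bins))
  }
  mode <- match.arg(mode)
  offs <- neighbors_full(mode)
  switch(class,
         glszm = glszm_matrix(roi$levels, offs, roi$n_bins),
         gldm  = gldm_matrix(roi$levels, offs, roi$n_bins),
         ngtdm = ngtdm_matrix(roi$levels, offs, roi$n_bins))
}

# symmetric co-occurrence counts for one direction
glcm_matrix <- function(lv, d, n_levels) {
  pr <- level_pairs(lv, d)
  P <- matrix(0, n_levels, n_levels)
  if (nrow(pr) == 0) return(P)
  tab <- tabulate(pr[, 1] + (pr[, 2] - 1L) * n_levels, nbins = n_levels^2)
  P <- matrix(tab, n_levels, n_levels)
  P + t(P)
}

# run-length counts for one direction: sort ROI voxels into lines along d,
# then break runs where the line, position or level changes
glrlm_matrix <- function(lv, d, n_levels) {
  ok <- !is.na(lv)
  if (!any(ok)) return(matrix(0, n_levels, 1))
  idx <- which(ok, arr.ind = TRUE)
  lev <- lv[ok]
  c0 <- which(d != 0L)[1]
  t_pos <- idx[, c0] * d[c0]
  key <- idx - outer(t_pos, d)
  K <- max(dim(lv)) + 2L
  B <- 4L * K
  kk <- (key[, 1] + K) + (key[, 2] + K) * B + (key[, 3] + K) * B^2
  o <- order(kk, t_pos)
  kk <- kk[o]; tp <- t_pos[o]; lev <- lev[o]
  n <- length(lev)
  newrun <- c(TRUE, kk[-1] != kk[-n] | diff(tp) != 1 | lev[-1] != lev[-n])
  rid <- cumsum(newrun)
  lens <- tabulate(rid)
  rl <- lev[newrun]
  jmax <- max(lens)
  tab <- tabulate(rl + (lens - 1L) * n_levels, nbins = n_levels * jmax)
  matrix(tab, n_levels, jmax)
}

# connected-component zone counts. Zones are components of the graph whose
# edges join adjacent ROI voxels of equal level, so all levels can be
# labelled at once: iterate minimum-label propagation over the edge list
# with pointer jumping until stable (O(log diameter) passes).
glszm_matrix <- function(lv, offsets, n_levels) {
  ok <- !is.na(lv)
  nvox <- sum(ok)
  if (nvox == 0) return(matrix(0, n_levels, 1))
  comp <- array(NA_integer_, dim(lv))
  comp[ok] <- seq_len(nvox)  # compact voxel index
  lev <- lv[ok]
  # half-offset edges between equal-level neighbors
  half <- offsets[seq_len(length(offsets) / 2)]
  aa <- integer(0); bb <- integer(0)
  for (d in half) {
    nb_lv <- shift_array(lv, d)
    nb_id <- shift_array(comp, d)
    sel <- ok & !is.na(nb_lv) & lv == nb_lv
    sel[is.na(sel)] <- FALSE
    aa <- c(aa, comp[sel]); bb <- c(bb, nb_id[sel])
  }
  lab <- seq_len(nvox)
  if (length(aa)) {
    ea <- c(aa, bb); eb <- c(bb, aa)  # both directions
    repeat {
      v <- lab[eb]
      o <- order(ea, v)
      first <- !duplicated(ea[o])
      tgt <- ea[o][first]
      minv <- v[o][first]
      new <- lab
      upd <- minv < new[tgt]
      new[tgt[upd]] <- minv[upd]
      new <- new[new]  # pointer jumping
      if (identical(new, lab)) break
      lab <- new
    }
  }
  sizes <- tabulate(lab, nvox)
  zone_ids <- which(sizes > 0)
  zones_size <- sizes[zone_ids]
  zones_level <- lev[zone_ids]  # representative label is a voxel index
  jmax <- max(zones_size)
  tab <- tabulate(zones_level + (zones_size - 1L) * n_levels, nbins = n_levels * jmax)
  matrix(tab, n_levels, jmax)
}

# dependence counts: j = 1 + number of neighbors with identical level
# (alpha = 0), center voxel included so j >= 1
gldm_matrix <- function(lv, offsets, n_levels) {
  ok <- !is.na(lv)
  if (!any(ok)) return(matrix(0, n_levels, 1))
  dep <- array(0L, dim(lv))
  for (d in offsets) {
    nb <- shift_array(lv, d)
    same <- ok & !is.na(nb) & lv == nb
    same[is.na(same)] <- FALSE
    dep <- dep + same
  }
  j <- dep[ok] + 1L
  lev <- lv[ok]
  jmax <- max(j)
  tab <- tabulate(lev + (j - 1L) * n_levels, nbins = n_levels * jmax)
  matrix(tab, n_levels, jmax)
}

# neighborhood gray-tone difference: per level, count of voxels and summed
# absolute difference from the mean of their in-ROI neighbors; voxels with
# no in-ROI neighbor are excluded
ngtdm_matrix <- function(lv, offsets, n_levels) {
  ok <- !is.na(lv)
  ssum <- array(0, dim(lv)); cnt <- array(0L, dim(lv))
  for (d in offsets) {
    nb <- shift_array(lv, d)
    has <- !is.na(nb)
    ssum[has] <- ssum[has] + nb[has]
    cnt <- cnt + has
  }
  valid <- ok & cnt > 0L
  n <- tabulate(lv[valid], nbins = n_levels)
  adiff <- abs(lv[valid] - ssum[valid] / cnt[valid])
  s <- numeric(n_levels)
  if (any(valid)) {
    agg <- rowsum(adiff, group = lv[valid])
    s[as.integer(rownames(agg))] <- agg[, 1]
  }
  n_valid <- sum(valid)
  list(n = n, s = s, p = if (n_valid > 0) n / n_valid else n * 0,
       n_valid = n_valid)
}
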