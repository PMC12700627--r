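test_that("NIfTI round trips preserve grid, values and anisotropic spacing", {
  arr <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  vol <- image_volume(arr, c(0.85, 0.85, 5.0))
  f <- tempfile(fileext = ".nii.gz")
  write_nifti(vol, f)
  back <- read_nifti(f)
  expect_equal(back$values, arr)
  # pixdim is single-precision in the NIfTI header
  expect_equal(back$spacing, c(0.85, 0.85, 5.0), tolerance = 1e-6)
  # mask round trip binarizes
  mf <- tempfile(fileext = ".nii.gz")
  write_nifti(roi_mask(arr > 0, c(1, 1, 2.5)), mf)
  mk <- read_nifti(mf, mask = TRUE)
  expect_identical(mk$values, arr > 0)
  # 4D input rejected
  f4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(3, 3, 3, 2))), f4)
  expect_error(read_nifti(f4), "3D")
  expect_error(read_nifti(tempfile()), "not found")
})

test_that("resampling is exact on identity, constants and linear ramps", {
  arr <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  img <- image_volume(arr, 1)
  mask <- roi_mask(array(TRUE, dim(arr)), 1)
  st <- list(name = "id", inplane_mm = 1, z_mm = 1, aggregation = "3D")
  out <- resample_pair(img, mask, st)
  expect_equal(out$image$values, arr, tolerance = 1e-12)
  # constant image stays constant under any target
  cimg <- image_volume(array(3, c(8, 8, 6)), 1)
  out2 <- resample_pair(cimg, mask, list(name = "c", inplane_mm = 0.7, z_mm = 1.4,
                                         aggregation = "3D"))
  expect_equal(max(abs(out2$image$values - 3)), 0, tolerance = 1e-10)
  # linear ramp along x: cubic splines reproduce linear functions, so
  # resampled samples lie on the same line
  ramp <- array(rep(seq_len(10), times = 4 * 4), c(10, 4, 4))
  rimg <- image_volume(ramp, 1)
  rmask <- roi_mask(array(TRUE, dim(ramp)), 1)
  half <- resample_pair(rimg, rmask, list(name = "h", inplane_mm = 0.5, z_mm = NA,
                                          aggregation = "2.5D"))
  xs <- radrep:::axis_coords(dim(half$image$values)[1], 0.5, half$image$origin[1])
  inside <- xs >= 0 & xs <= 9
  expect_equal(half$image$values[inside, 1, 1], 1 + xs[inside], tolerance = 1e-9)
})

test_that("z-preserving settings leave the z axis untouched", {
  arr <- array(rnorm(6 * 6 * 5), c(6, 6, 5))
  img <- image_volume(arr, c(1, 1, 3))
  mask <- roi_mask(array(TRUE, dim(arr)), c(1, 1, 3))
  out <- resample_pair(img, mask, "L2i")
  expect_equal(dim(out$image$values)[3], 5)
  expect_equal(out$image$spacing[3], 3)
})

test_that("resegmentation retains exactly the closed HU window", {
  arr <- array(c(-60, 0, 350, 351), c(4, 1, 1))
  img <- image_volume(arr, 1)
  mask <- roi_mask(array(TRUE, c(4, 1, 1)), 1)
  out <- resegment(img, mask, c(-50, 350))
  expect_equal(sum(out$values), 2)
  expect_true(all(arr[out$values] >= -50 & arr[out$values] <= 350))
  # all-in-window leaves the mask unchanged
  img2 <- image_volume(array(100, c(3, 3, 3)), 1)
  mask2 <- roi_mask(array(TRUE, c(3, 3, 3)), 1)
  expect_identical(resegment(img2, mask2)$values, mask2$values)
  expect_error(resegment(img, mask, c(10, -10)), "lo <= hi")
  expect_error(resegment(img, mask, c(1000, 2000)), "empty")
})

test_that("discretization follows the fixed-bin-count formula", {
  vals <- array(0:10, c(11, 1, 1))
  img <- image_volume(vals, 1)
  mask <- roi_mask(array(TRUE, c(11, 1, 1)), 1)
  d2 <- discretize(img, mask, n_bins = 2)
  lv <- d2$levels[!is.na(d2$levels)]
  expect_equal(lv, ifelse(0:10 < 5, 1L, 2L))
  # bin width (max-min)/n_bins
  img24 <- image_volume(array(seq(0, 24, length.out = 25), c(25, 1, 1)), 1)
  mask24 <- roi_mask(array(TRUE, c(25, 1, 1)), 1)
  d24 <- discretize(img24, mask24, n_bins = 24)
  expect_equal(diff(d24$bin_edges)[1], 1.0)
  # constant ROI -> all level 1
  dc <- discretize(image_volume(array(5, c(3, 3, 3)), 1),
                   roi_mask(array(TRUE, c(3, 3, 3)), 1), 24)
  expect_true(all(dc$levels[!is.na(dc$levels)] == 1L))
  expect_error(discretize(img, mask, n_bins = 1), "n_bins")
})

test_that("first-order features match hand computation and an independent oracle", {
  d <- droi_from_levels(array(1:4, c(4, 1, 1)))
  fv <- first_order_features(img3(array(1:4, c(4, 1, 1))), d)
  expect_equal(unname(fv["firstorder_Mean"]), 2.5)
  expect_equal(unname(fv["firstorder_Variance"]), 1.25)
  expect_equal(unname(fv["firstorder_Range"]), 3)
  # constant ROI
  dc <- discretize(img3(array(7, c(3, 3, 2))), msk3(array(TRUE, c(3, 3, 2))), 24)
  fvc <- first_order_features(img3(array(7, c(3, 3, 2))), dc)
  expect_equal(unname(fvc[c("firstorder_Mean", "firstorder_Median",
                            "firstorder_Minimum", "firstorder_Maximum")]),
               rep(7, 4))
  expect_equal(unname(fvc["firstorder_Variance"]), 0)
  expect_equal(unname(fvc["firstorder_Entropy"]), 0)
  expect_equal(unname(fvc["firstorder_Uniformity"]), 1)
  # histogram oracle over random ROIs
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(50, 100, 20)
    img <- img3(array(x, c(50, 1, 1)))
    dd <- discretize(img, msk3(array(TRUE, c(50, 1, 1))), 8)
    fv <- first_order_features(img, dd)
    expect_equal(unname(fv["firstorder_Mean"]), mean(x))
    expect_equal(unname(fv["firstorder_Variance"]), mean((x - mean(x))^2))
    expect_equal(unname(fv["firstorder_Energy"]), sum(x^2))
    expect_equal(unname(fv["firstorder_Median"]), median(x))
    expect_equal(unname(fv["firstorder_10Percentile"]), quantile(x, 0.1, names = FALSE))
    expect_equal(unname(fv["firstorder_RootMeanSquared"]), sqrt(mean(x^2)))
    p <- tabulate(dd$levels[!is.na(dd$levels)], 8) / 50
    expect_equal(unname(fv["firstorder_Uniformity"]), sum(p^2))
    expect_equal(unname(fv["firstorder_Entropy"]), -sum(p[p > 0] * log2(p[p > 0])))
  }
})

test_that("texture matrices match spec'd hand enumerations", {
  # GLCM on a 2x2 slice with columns of levels [[1,2],[1,2]] along y
  lv <- array(NA_integer_, c(2, 2, 1))
  lv[, , 1] <- matrix(c(1L, 1L, 2L, 2L), 2, 2)  # lv[x, y]: y=1 col is 1s, y=2 col is 2s
  d <- droi_from_levels(lv)
  P <- build_texture_matrix(d, "glcm", direction = c(0, 1, 0))
  expect_equal(P[1, 2], 2)
  expect_equal(P[2, 1], 2)
  expect_equal(P[1, 1] + P[2, 2], 0)
  # GLRLM along z for a 1x1x4 line (1,1,2,2): one run of each level, length 2
  lvz <- array(c(1L, 1L, 2L, 2L), c(1, 1, 4))
  dz <- droi_from_levels(lvz)
  R <- build_texture_matrix(dz, "glrlm", direction = c(0, 0, 1))
  expect_equal(R[1, 2], 1)
  expect_equal(R[2, 2], 1)
  expect_equal(sum(R), 2)
  # GLSZM of a constant single-slice ROI: one zone of size N
  lvc <- array(1L, c(3, 4, 1))
  dc <- droi_from_levels(lvc)
  Z <- build_texture_matrix(dc, "glszm", mode = "2.5D")
  expect_equal(Z[1, 12], 1)
  expect_equal(sum(Z), 1)
})

test_that("all matrix builders match brute-force oracles on random ROIs", {
  dirs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0), c(-1, 1, 0),
               c(1, 0, 1), c(0, 1, -1), c(1, 1, 1), c(-1, 1, 1))
  for (s in 1:8) {
    d <- random_droi(s, dims = c(5, 4, 4), n_levels = 4)
    lv <- d$levels
    for (dir in dirs[seq(1 + s %% 3, 9, by = 3)]) {
      expect_equal(build_texture_matrix(d, "glcm", direction = dir),
                   oracle_glcm(lv, as.integer(dir), 4), info = sprintf("glcm seed %d", s))
      G1 <- build_texture_matrix(d, "glrlm", direction = dir)
      G2 <- oracle_glrlm(lv, as.integer(dir), 4)
      expect_equal(G1[, seq_len(ncol(G2)), drop = FALSE], G2,
                   info = sprintf("glrlm seed %d", s))
    }
    for (mode in c("2.5D", "3D")) {
      Z1 <- build_texture_matrix(d, "glszm", mode = mode)
      Z2 <- oracle_glszm(lv, mode, 4)
      expect_equal(Z1[, seq_len(ncol(Z2)), drop = FALSE], Z2,
                   info = sprintf("glszm seed %d %s", s, mode))
      D1 <- build_texture_matrix(d, "gldm", mode = mode)
      D2 <- oracle_gldm(lv, mode, 4)
      expect_equal(D1[, seq_len(ncol(D2)), drop = FALSE], D2,
                   info = sprintf("gldm seed %d %s", s, mode))
      N1 <- build_texture_matrix(d, "ngtdm", mode = mode)
      N2 <- oracle_ngtdm(lv, mode, 4)
      expect_equal(N1$n, N2$n, info = sprintf("ngtdm seed %d %s", s, mode))
      expect_equal(N1$s, N2$s, info = sprintf("ngtdm seed %d %s", s, mode))
      expect_equal(N1$n_valid, N2$n_valid)
    }
  }
})

test_that("matrix conservation invariants hold", {
  for (s in c(3, 17)) {
    d <- random_droi(s, dims = c(6, 6, 4), n_levels = 5)
    n_vox <- sum(!is.na(d$levels))
    for (mode in c("2.5D", "3D")) {
      # GLDM entries sum to the voxel count
      expect_equal(sum(build_texture_matrix(d, "gldm", mode = mode)), n_vox)
      # GLSZM zone sizes weighted by count sum to the voxel count
      Z <- build_texture_matrix(d, "glszm", mode = mode)
      expect_equal(sum(Z %*% seq_len(ncol(Z))), n_vox)
    }
    # GLRLM: total run length equals the voxel count per direction
    for (dir in list(c(1, 0, 0), c(1, 1, 1))) {
      R <- build_texture_matrix(d, "glrlm", direction = dir)
      expect_equal(sum(R %*% seq_len(ncol(R))), n_vox)
    }
    # NGTDM counts cover all voxels with at least one in-ROI neighbor
    N <- build_texture_matrix(d, "ngtdm", mode = "3D")
    expect_lte(sum(N$n), n_vox)
    expect_equal(sum(N$p), if (N$n_valid > 0) 1 else 0)
  }
})

test_that("directional aggregation averages per-direction features (oracle check)", {
  d <- random_droi(23, dims = c(4, 4, 4), n_levels = 3, p_roi = 0.9)
  agg <- aggregate_texture(d, "glcm", "3D")
  dirs <- radrep:::directions_3d()
  per_dir <- sapply(dirs, function(dir) {
    P <- oracle_glcm(d$levels, as.integer(dir), 3)
    radrep:::glcm_features(P)
  })
  expect_equal(agg, rowMeans(per_dir), tolerance = 1e-12)
})

test_that("single-slice 2.5D texture features equal the 2D slice features", {
  d <- random_droi(5, dims = c(6, 6, 1), n_levels = 4, p_roi = 0.9)
  # with one slice, merging over slices is a no-op: the 2.5D matrices ARE
  # the single-slice 2D matrices
  z25 <- build_texture_matrix(d, "glszm", mode = "2.5D")
  z2d <- oracle_glszm(d$levels, "2.5D", 4)
  expect_equal(z25[, seq_len(ncol(z2d)), drop = FALSE], z2d)
  f25 <- aggregate_texture(d, "glszm", "2.5D")
  expect_true(all(is.finite(f25)))
})

test_that("degenerate ROIs flag undefined features instead of crashing", {
  # constant ROI: zero contrast and undefined correlation-type features
  dc <- droi_from_levels(array(1L, c(4, 4, 2)))
  fv <- aggregate_texture(dc, "glcm", "3D")
  expect_equal(unname(fv["glcm_Contrast"]), 0)
  expect_true(is.na(fv["glcm_Correlation"]))
  f25 <- aggregate_texture(dc, "glcm", "2.5D")
  expect_equal(unname(f25["glcm_Contrast"]), 0)
  # single isolated voxel: no pairs in any direction
  lone <- droi_from_levels(array(c(1L, NA, NA, NA), c(2, 2, 1)))
  fl <- aggregate_texture(lone, "glcm", "2.5D")
  expect_true(all(is.na(fl)))
})

test_that("full extraction yields tagged 93-feature blocks per ROI and setting", {
  p <- generate_phantom(phantom_spec(grid_shape = c(24, 24, 12),
                                     tumor_radii_mm = c(7, 7, 5.5),
                                     shell_radii_mm = c(13, 13, 7),
                                     gap_mm = 1.5, seed = 19))
  tab <- extract_all(p$image, list(tumor = p$tumor, parenchyma = p$parenchyma),
                     settings = c("L2i", "A3"))
  expect_equal(nrow(tab), 2 * 2 * 93)
  expect_setequal(unique(tab$extractor), c("L2i", "A3"))
  expect_setequal(unique(tab$roi), c("tumor", "parenchyma"))
  expect_setequal(unique(tab$feature), feature_registry()$feature)
  # deterministic
  tab2 <- extract_all(p$image, list(tumor = p$tumor, parenchyma = p$parenchyma),
                      settings = c("L2i", "A3"))
  expect_identical(tab, tab2)
  expect_error(extract_all(p$image, list(tumor = p$tumor), settings = character(0)),
               "nonempty")
})
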