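# Texture feature formulas, one function per matrix class. Each takes raw
# counts and returns a named numeric vector (qualified names). Features that
# are mathematically undefined on the input (e.g. correlation of a constant
# ROI) are returned as NA, never silently zeroed.

glcm_features <- function(P) {
  nm <- paste0("glcm_", feature_registry_names("glcm"))
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  Nb <- nrow(P)
  tot <- sum(P)
  if (tot == 0) return(out)
  p <- P / tot
  i <- matrix(seq_len(Nb), Nb, Nb)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  present <- which(px + py > 0)
  Ng <- length(present)
  mux <- sum(i * p); muy <- sum(j * p)
  sigx <- sqrt(sum((i - mux)^2 * p)); sigy <- sqrt(sum((j - muy)^2 * p))
  # diagonal (difference) and cross-diagonal (sum) distributions
  kdiff <- 0:(Nb - 1)
  pxmy <- vapply(kdiff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  ksum <- 2:(2 * Nb)
  pxpy <- vapply(ksum, function(k) sum(p[(i + j) == k]), numeric(1))
  DA <- sum(kdiff * pxmy)
  HX <- -sum(xlog2(px)); HY <- -sum(xlog2(py))
  HXY <- -sum(xlog2(p))
  pxy_prod <- px[i] * py[j]  # matrix of px(i)py(j)
  sel <- p > 0
  HXY1 <- -sum(p[sel] * log2(pxy_prod[sel]))
  selp <- pxy_prod > 0
  HXY2 <- -sum(pxy_prod[selp] * log2(pxy_prod[selp]))

  out["glcm_Autocorrelation"] <- sum(i * j * p)
  out["glcm_JointAverage"] <- mux
  out["glcm_ClusterProminence"] <- sum((i + j - mux - muy)^4 * p)
  out["glcm_ClusterShade"] <- sum((i + j - mux - muy)^3 * p)
  out["glcm_ClusterTendency"] <- sum((i + j - mux - muy)^2 * p)
  out["glcm_Contrast"] <- sum((i - j)^2 * p)
  out["glcm_Correlation"] <- if (sigx > 0 && sigy > 0)
    (sum(i * j * p) - mux * muy) / (sigx * sigy) else NA_real_
  out["glcm_DifferenceAverage"] <- DA
  out["glcm_DifferenceEntropy"] <- -sum(xlog2(pxmy))
  out["glcm_DifferenceVariance"] <- sum((kdiff - DA)^2 * pxmy)
  out["glcm_Id"] <- sum(p / (1 + abs(i - j)))
  out["glcm_Idm"] <- sum(p / (1 + (i - j)^2))
  out["glcm_Idmn"] <- sum(p / (1 + ((i - j) / Nb)^2))
  out["glcm_Idn"] <- sum(p / (1 + abs(i - j) / Nb))
  maxhxhy <- max(HX, HY)
  out["glcm_Imc1"] <- if (maxhxhy > 0) (HXY - HXY1) / maxhxhy else 0
  imc2sq <- 1 - exp(-2 * (HXY2 - HXY))
  out["glcm_Imc2"] <- sqrt(max(0, imc2sq))
  offdiag <- abs(i - j) > 0
  out["glcm_InverseVariance"] <- sum(p[offdiag] / (i - j)[offdiag]^2)
  out["glcm_JointEnergy"] <- sum(p^2)
  out["glcm_JointEntropy"] <- HXY
  out["glcm_MCC"] <- glcm_mcc(p, px, py, present)
  out["glcm_MaximumProbability"] <- max(p)
  out["glcm_SumAverage"] <- sum(ksum * pxpy)
  out["glcm_SumEntropy"] <- -sum(xlog2(pxpy))
  out["glcm_SumSquares"] <- sum((i - mux)^2 * p)
  out
}

# maximal correlation coefficient: sqrt of the second-largest eigenvalue of
# Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k)), over levels present
glcm_mcc <- function(p, px, py, present) {
  if (length(present) < 2) return(1)
  ps <- p[present, present, drop = FALSE]
  pxs <- px[present]; pys <- py[present]
  A <- sweep(ps, 1, pxs, "/")
  B <- sweep(ps, 2, pys, "/")
  Q <- A %*% t(B)
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(max(0, ev[2]))
}

# shared machinery for the level x size-type matrices (GLRLM runs, GLSZM
# zones, GLDM dependences): emphases over i (gray level) and j (size)
lvlsize_stats <- function(P) {
  Ns <- sum(P)
  Nb <- nrow(P); J <- ncol(P)
  i <- matrix(seq_len(Nb), Nb, J)
  j <- matrix(seq_len(J), Nb, J, byrow = TRUE)
  p <- P / Ns
  list(P = P, p = p, i = i, j = j, Ns = Ns,
       ri = rowSums(P), cj = colSums(P),
       mu_i = sum(i * p), mu_j = sum(j * p))
}

glrlm_features <- function(P, n_voxels) {
  nm <- paste0("glrlm_", feature_registry_names("glrlm"))
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  if (sum(P) == 0) return(out)
  s <- lvlsize_stats(P)
  Nr <- s$Ns
  out["glrlm_ShortRunEmphasis"] <- sum(s$P / s$j^2) / Nr
  out["glrlm_LongRunEmphasis"] <- sum(s$P * s$j^2) / Nr
  out["glrlm_GrayLevelNonUniformity"] <- sum(s$ri^2) / Nr
  out["glrlm_GrayLevelNonUniformityNormalized"] <- sum(s$ri^2) / Nr^2
  out["glrlm_RunLengthNonUniformity"] <- sum(s$cj^2) / Nr
  out["glrlm_RunLengthNonUniformityNormalized"] <- sum(s$cj^2) / Nr^2
  out["glrlm_RunPercentage"] <- Nr / n_voxels
  out["glrlm_GrayLevelVariance"] <- sum((s$i - s$mu_i)^2 * s$p)
  out["glrlm_RunVariance"] <- sum((s$j - s$mu_j)^2 * s$p)
  out["glrlm_RunEntropy"] <- -sum(xlog2(s$p))
  out["glrlm_LowGrayLevelRunEmphasis"] <- sum(s$P / s$i^2) / Nr
  out["glrlm_HighGrayLevelRunEmphasis"] <- sum(s$P * s$i^2) / Nr
  out["glrlm_ShortRunLowGrayLevelEmphasis"] <- sum(s$P / (s$i^2 * s$j^2)) / Nr
  out["glrlm_ShortRunHighGrayLevelEmphasis"] <- sum(s$P * s$i^2 / s$j^2) / Nr
  out["glrlm_LongRunLowGrayLevelEmphasis"] <- sum(s$P * s$j^2 / s$i^2) / Nr
  out["glrlm_LongRunHighGrayLevelEmphasis"] <- sum(s$P * s$i^2 * s$j^2) / Nr
  out
}

glszm_features <- function(P, n_voxels) {
  nm <- paste0("glszm_", feature_registry_names("glszm"))
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  if (sum(P) == 0) return(out)
  s <- lvlsize_stats(P)
  Nz <- s$Ns
  out["glszm_SmallAreaEmphasis"] <- sum(s$P / s$j^2) / Nz
  out["glszm_LargeAreaEmphasis"] <- sum(s$P * s$j^2) / Nz
  out["glszm_GrayLevelNonUniformity"] <- sum(s$ri^2) / Nz
  out["glszm_GrayLevelNonUniformityNormalized"] <- sum(s$ri^2) / Nz^2
  out["glszm_SizeZoneNonUniformity"] <- sum(s$cj^2) / Nz
  out["glszm_SizeZoneNonUniformityNormalized"] <- sum(s$cj^2) / Nz^2
  out["glszm_ZonePercentage"] <- Nz / n_voxels
  out["glszm_GrayLevelVariance"] <- sum((s$i - s$mu_i)^2 * s$p)
  out["glszm_ZoneVariance"] <- sum((s$j - s$mu_j)^2 * s$p)
  out["glszm_ZoneEntropy"] <- -sum(xlog2(s$p))
  out["glszm_LowGrayLevelZoneEmphasis"] <- sum(s$P / s$i^2) / Nz
  out["glszm_HighGrayLevelZoneEmphasis"] <- sum(s$P * s$i^2) / Nz
  out["glszm_SmallAreaLowGrayLevelEmphasis"] <- sum(s$P / (s$i^2 * s$j^2)) / Nz
  out["glszm_SmallAreaHighGrayLevelEmphasis"] <- sum(s$P * s$i^2 / s$j^2) / Nz
  out["glszm_LargeAreaLowGrayLevelEmphasis"] <- sum(s$P * s$j^2 / s$i^2) / Nz
  out["glszm_LargeAreaHighGrayLevelEmphasis"] <- sum(s$P * s$i^2 * s$j^2) / Nz
  out
}

gldm_features <- function(P, n_voxels) {
  nm <- paste0("gldm_", feature_registry_names("gldm"))
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  if (sum(P) == 0) return(out)
  s <- lvlsize_stats(P)
  Nz <- s$Ns  # equals n_voxels: every ROI voxel has dependence >= 1
  out["gldm_SmallDependenceEmphasis"] <- sum(s$P / s$j^2) / Nz
  out["gldm_LargeDependenceEmphasis"] <- sum(s$P * s$j^2) / Nz
  out["gldm_GrayLevelNonUniformity"] <- sum(s$ri^2) / Nz
  out["gldm_DependenceNonUniformity"] <- sum(s$cj^2) / Nz
  out["gldm_DependenceNonUniformityNormalized"] <- sum(s$cj^2) / Nz^2
  out["gldm_GrayLevelVariance"] <- sum((s$i - s$mu_i)^2 * s$p)
  out["gldm_DependenceVariance"] <- sum((s$j - s$mu_j)^2 * s$p)
  out["gldm_DependenceEntropy"] <- -sum(xlog2(s$p))
  out["gldm_LowGrayLevelEmphasis"] <- sum(s$P / s$i^2) / Nz
  out["gldm_HighGrayLevelEmphasis"] <- sum(s$P * s$i^2) / Nz
  out["gldm_SmallDependenceLowGrayLevelEmphasis"] <- sum(s$P / (s$i^2 * s$j^2)) / Nz
  out["gldm_SmallDependenceHighGrayLevelEmphasis"] <- sum(s$P * s$i^2 / s$j^2) / Nz
  out["gldm_LargeDependenceLowGrayLevelEmphasis"] <- sum(s$P * s$j^2 / s$i^2) / Nz
  out["gldm_LargeDependenceHighGrayLevelEmphasis"] <- sum(s$P * s$i^2 * s$j^2) / Nz
  out
}

ngtdm_features <- function(ng) {
  nm <- paste0("ngtdm_", feature_registry_names("ngtdm"))
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  if (ng$n_valid == 0) return(out)
  p <- ng$p; s <- ng$s
  lev <- seq_along(p)
  nz <- which(p > 0)
  Ngp <- length(nz)
  Nvp <- ng$n_valid
  denom_coarse <- sum(p * s)
  out["ngtdm_Coarseness"] <- if (denom_coarse > 0) 1 / denom_coarse else 1e6
  if (Ngp > 1) {
    ii <- matrix(lev[nz], Ngp, Ngp); jj <- t(ii)
    pi_ <- p[nz]
    pij <- outer(pi_, pi_)
    out["ngtdm_Contrast"] <- (sum(pij * (ii - jj)^2) / (Ngp * (Ngp - 1))) * (sum(s) / Nvp)
    busy_den <- sum(abs(outer(lev[nz] * pi_, lev[nz] * pi_, "-")))
    out["ngtdm_Busyness"] <- if (busy_den > 0) sum(p * s) / busy_den else 0
    si <- s[nz]
    out["ngtdm_Complexity"] <- sum(abs(ii - jj) * (outer(pi_ * si, pi_ * si, function(a, b) a + b)) /
                                     (outer(pi_, pi_, "+"))) / Nvp
    sum_s <- sum(s)
    out["ngtdm_Strength"] <- if (sum_s > 0) sum(outer(pi_, pi_, "+") * (ii - jj)^2) / sum_s else 0
  } else {
    out["ngtdm_Contrast"] <- 0
    out["ngtdm_Busyness"] <- 0
    out["ngtdm_Complexity"] <- 0
    out["ngtdm_Strength"] <- 0
  }
  out
}

# helper: registry names for a class, in registry order
feature_registry_names <- local({
  cache <- NULL
  function(class) {
    if (is.null(cache)) cache <<- feature_registry()
    cache$name[cache$class == class]
  }
})
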