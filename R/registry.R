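#' Feature registry
#'
#' Enumerates the 93 intensity and texture features computed by the package:
#' 18 first-order (histogram) features plus five texture classes defined on
#' gray-level matrices (GLCM 24, GLRLM 16, GLSZM 16, GLDM 14, NGTDM 5).
#' Feature names follow the common open-source radiomics nomenclature, with
#' each name prefixed by its class.
#'
#' @return A data.frame with columns `feature` (qualified name, e.g.
#'   `"glcm_Contrast"`), `class` and `name`.
#' @export
#' @examples
#' table(feature_registry()$class)
feature_registry <- function() {
  classes <- list(
    firstorder = c(
      "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
      "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
      "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
      "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity"),
    glcm = c(
      "Autocorrelation", "ClusterProminence", "ClusterShade",
      "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
      "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
      "Imc1", "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
      "JointEntropy", "MCC", "MaximumProbability", "SumAverage",
      "SumEntropy", "SumSquares"),
    glrlm = c(
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
      "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
      "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
      "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
      "ShortRunLowGrayLevelEmphasis"),
    glszm = c(
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
      "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
      "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
      "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
      "ZoneEntropy", "ZonePercentage", "ZoneVariance"),
    gldm = c(
      "DependenceEntropy", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "DependenceVariance",
      "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
      "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
      "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
      "SmallDependenceLowGrayLevelEmphasis"),
    ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
  )
  out <- do.call(rbind, lapply(names(classes), function(cl) {
    data.frame(feature = paste0(cl, "_", classes[[cl]]),
               class = cl, name = classes[[cl]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Extractor settings registry
#'
#' The eight feature-extraction settings studied by the pipeline. Each
#' setting fixes the resampling target (in-plane and through-plane voxel
#' size) and the texture aggregation mode. The naming scheme encodes the
#' in-plane resolution ("L" = 1 mm, "S" = 0.85 mm, "A" = anisotropic
#' 0.85 x 0.85 x 2.5 mm), the aggregation ("2" = 2.5D, "3" = 3D), and an
#' "i" suffix for in-plane-only resampling that preserves the native z
#' resolution (only meaningful with 2.5D aggregation, which never compares
#' voxels across slices).
#'
#' @return A data.frame with columns `name`, `inplane_mm`, `z_mm` (`NA`
#'   means "preserve the native z spacing") and `aggregation`
#'   (`"2.5D"` or `"3D"`).
#' @export
#' @examples
#' extractor_settings()
extractor_settings <- function() {
  data.frame(
    name        = c("L2i", "L2", "L3", "S2i", "S2", "S3", "A2", "A3"),
    inplane_mm  = c(1, 1, 1, 0.85, 0.85, 0.85, 0.85, 0.85),
    z_mm        = c(NA, 1, 1, NA, 0.85, 0.85, 2.5, 2.5),
    aggregation = c("2.5D", "2.5D", "3D", "2.5D", "2.5D", "3D", "2.5D", "3D"),
    stringsAsFactors = FALSE
  )
}

#' List the extraction registry
#'
#' Convenience accessor bundling the extractor settings and feature
#' definitions used throughout the pipeline.
#'
#' @return A list with elements `settings` (8-row data.frame) and
#'   `features` (93-row data.frame).
#' @export
list_registry <- function() {
  list(settings = extractor_settings(), features = feature_registry())
}
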