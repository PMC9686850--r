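#' Feature bank configuration
#'
#' Controls the 884-feature-per-ROI radiomics bank. The family allocation is
#' GLCM 22 statistics x 8 directions x 4 offsets = 704, GLRLM 11 x 4 = 44,
#' NGTDM 5, intensity direct 56, intensity histogram 40, histogram Gaussian
#' fit 18 and shape 17.
#'
#' @param n_gray_levels number of gray levels for ROI-wise min-max
#'   discretization (>= 8).
#' @param glcm_directions in-plane angles in degrees.
#' @param glcm_offsets voxel displacement magnitudes.
#' @param glrlm_directions in-plane run directions in degrees.
#' @param local_window voxel radius of the local-statistics window
#'   (1 means 3x3x3).
#' @param gaussfit_components numbers of mixture components fitted to the
#'   intensity histogram.
#' @param hull_directions number of quasi-uniform directions used for the
#'   support-function hull quantities (mean breadth, hull volume, diameter).
#' @param min_voxels ROIs smaller than this emit all-null features.
#' @return An object of class `rd_bank_config`.
#' @export
feature_bank_config <- function(n_gray_levels = 64,
                                glcm_directions = c(0, 45, 90, 135, 180, 225, 270, 315),
                                glcm_offsets = c(1, 4, 7, 10),
                                glrlm_directions = c(0, 45, 90, 135),
                                local_window = 1,
                                gaussfit_components = 1:3,
                                hull_directions = 100,
                                min_voxels = 27) {
  stopifnot(n_gray_levels >= 8,
            !anyDuplicated(glcm_directions), !anyDuplicated(glcm_offsets))
  structure(list(n_gray_levels = as.integer(n_gray_levels),
                 glcm_directions = glcm_directions,
                 glcm_offsets = glcm_offsets,
                 glrlm_directions = glrlm_directions,
                 local_window = as.integer(local_window),
                 gaussfit_components = gaussfit_components,
                 hull_directions = as.integer(hull_directions),
                 min_voxels = as.integer(min_voxels)),
            class = "rd_bank_config")
}

GLCM_STATS <- c("AutoCorrelation", "Contrast", "Correlation",
                "ClusterProminence", "ClusterShade", "ClusterTendency",
                "Dissimilarity", "Energy", "Entropy", "Homogeneity1",
                "Homogeneity2", "IMC1", "IMC2", "IDMN", "InverseVariance",
                "MaxProbability", "SumAverage", "SumEntropy", "SumVariance",
                "DifferenceEntropy", "DifferenceVariance", "Variance")

GLRLM_STATS <- c("SRE", "LRE", "GLN", "RLN", "RP",
                 "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE")

NGTDM_STATS <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")

ID_GLOBAL_STATS <- c("Mean", "Median", "Min", "Max", "Range", "SD", "Variance",
                     "Skewness", "Kurtosis", "Energy", "Entropy", "MAD", "RMS",
                     "Uniformity", "P10", "P25", "P75", "P90", "IQR",
                     "0.025Quantile", "0.975Quantile")

ID_LOCAL_STATS <- c("Mean", "Std", "Range", "Entropy", "Median", "Min", "Max")
ID_LOCAL_AGGS <- c("Max", "Min", "Mean", "Median", "Std")

GOH_PROBS <- c(0.025, seq(0.05, 0.95, by = 0.05), 0.975)
GOH_STATS <- c("Mean", "Median", "Mode", "SD", "MAD", "RobustMAD", "Skewness",
               "Kurtosis", "Energy", "Entropy", "Uniformity", "Range", "IQR",
               "CV", "QCD", "Min", "Max", "Sum", "Count")

SHAPE_STATS <- c("Volume", "SurfaceArea", "Surface2VolumeRatio", "Sphericity",
                 "Compactness1", "Compactness2", "SphericalDisproportion",
                 "Max3DDiameter", "MeanBreadth", "ConvexHullVolume3D",
                 "ConvexDeficiency", "NumberOfObjects", "Elongation",
                 "Flatness", "Roundness", "Orientation", "MaxAxialArea")

fmt_prob <- function(p) sub("0+$", "", sub("\\.$", "", sprintf("%.3f", p)))

gaussfit_names <- function(components) {
  unlist(lapply(components, function(k) {
    if (k == 1) paste0("F6.IHGaussFit1Gauss", c("Mean", "Std", "Amplitude"))
    else as.vector(t(outer(seq_len(k), c("Mean", "Std", "Amplitude"),
                           function(j, s) sprintf("F6.IHGaussFit%dGauss%d%s", k, j, s))))
  }))
}

#' Names of the 884-feature bank
#'
#' @param cfg a [feature_bank_config()].
#' @return Character vector of length 884 following the
#'   `F<k>.<Family><params>_<Stat>` convention (no ROI prefix).
#' @export
feature_bank_names <- function(cfg = feature_bank_config()) {
  goh <- c(paste0("F1.GOH", fmt_prob(GOH_PROBS), "Quantile"),
           paste0("F1.GOH_", GOH_STATS))
  glcm <- unlist(lapply(cfg$glcm_directions, function(d)
    unlist(lapply(cfg$glcm_offsets, function(o)
      sprintf("F2.GLCM25%d.%d_%s", d, o, GLCM_STATS)))))
  glrlm <- unlist(lapply(cfg$glrlm_directions, function(d)
    sprintf("F3.GLRLM25%d_%s", d, GLRLM_STATS)))
  idg <- paste0("F4.ID_", ID_GLOBAL_STATS)
  idl <- as.vector(t(outer(ID_LOCAL_STATS, ID_LOCAL_AGGS,
                           function(s, a) paste0("F4.ID_Local", s, a))))
  ngtdm <- paste0("F5.NID25_", NGTDM_STATS)
  gf <- gaussfit_names(cfg$gaussfit_components)
  shp <- paste0("F8.Shape", SHAPE_STATS)
  c(goh, glcm, glrlm, idg, idl, ngtdm, gf, shp)
}

# in-plane displacement (dx, dy) for a direction in degrees
direction_offset <- function(deg) {
  rad <- deg * pi / 180
  c(round(cos(rad)), round(sin(rad)))
}

#' Discretize in-mask intensities to integer gray levels
#'
#' ROI-wise min-max binning into `1..n_gray_levels`; a constant region maps
#' entirely to level 1. The maximum maps to the top level.
#'
#' @param image numeric 3-D array (raw HU).
#' @param mask logical array of the same shape.
#' @param n_gray_levels number of levels (>= 8).
#' @return Integer array: 0 outside the mask, 1..G inside.
#' @export
discretize <- function(image, mask, n_gray_levels = 64) {
  stopifnot(any(mask), n_gray_levels >= 8)
  lev <- array(0L, dim = dim(image))
  x <- image[mask]
  rng <- range(x)
  if (rng[1] == rng[2]) {
    lev[mask] <- 1L
  } else {
    lev[mask] <- pmin(n_gray_levels,
                      floor((x - rng[1]) / (rng[2] - rng[1]) * n_gray_levels) + 1L)
  }
  lev
}
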