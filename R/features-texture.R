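# Texture families: GLCM, GLRLM and NGTDM in the 2.5D convention —
# per-axial-slice matrices accumulated across slices before statistics.

glcm_stats_from_matrix <- function(M) {
  tot <- sum(M)
  if (tot == 0) return(setNames(rep(NA_real_, length(GLCM_STATS)), GLCM_STATS))
  P <- (M + t(M))
  P <- P / sum(P)
  G <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(G) * px); muy <- sum(seq_len(G) * py)
  sx <- sqrt(sum((seq_len(G) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(G) - muy)^2 * py))
  lg <- function(v) ifelse(v > 0, log2(v), 0)
  ent <- -sum(P * lg(P))
  hx <- -sum(px * lg(px)); hy <- -sum(py * lg(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * lg(pxy))
  hxy2 <- -sum(pxy * lg(pxy))
  # sum / difference distributions
  ks <- 2:(2 * G)
  psum <- vapply(ks, function(k) sum(P[i + j == k]), numeric(1))
  kd <- 0:(G - 1)
  pdiff <- vapply(kd, function(k) sum(P[abs(i - j) == k]), numeric(1))
  sa <- sum(ks * psum)
  mud <- sum(kd * pdiff)
  c(AutoCorrelation = sum(i * j * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = if (sx > 0 && sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 0,
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Dissimilarity = sum(abs(i - j) * P),
    Energy = sum(P^2),
    Entropy = ent,
    Homogeneity1 = sum(P / (1 + abs(i - j))),
    Homogeneity2 = sum(P / (1 + (i - j)^2)),
    IMC1 = if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0,
    IMC2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - ent)))),
    IDMN = sum(P / (1 + (i - j)^2 / G^2)),
    InverseVariance = sum(P[i != j] / (i - j)[i != j]^2),
    MaxProbability = max(P),
    SumAverage = sa,
    SumEntropy = -sum(psum * lg(psum)),
    SumVariance = sum((ks - sa)^2 * psum),
    DifferenceEntropy = -sum(pdiff * lg(pdiff)),
    DifferenceVariance = sum((kd - mud)^2 * pdiff),
    Variance = sx^2)
}

#' GLCM statistics (2.5D) for one direction/offset pair
#'
#' Co-occurrence counts are formed per axial slice at the in-plane
#' displacement given by `direction` (degrees) and `offset` (voxels),
#' accumulated over slices, symmetrized and normalized; 22 Haralick-style
#' statistics are returned. Opposite directions (theta and theta + 180)
#' yield identical values by construction.
#'
#' @param levels integer gray-level array (0 outside the mask), as returned
#'   by [discretize()].
#' @param direction in-plane angle in degrees (multiple of 45).
#' @param offset displacement magnitude in voxels (>= 1).
#' @param n_gray_levels number of gray levels used in `levels`.
#' @return Named numeric vector of 22 statistics (all `NA` if no voxel pair
#'   exists at this displacement).
#' @export
glcm_features_25d <- function(levels, direction, offset,
                              n_gray_levels = max(levels)) {
  stopifnot(offset >= 1)
  d <- direction_offset(direction)
  M <- cpp_glcm(as.integer(levels), as.integer(dim(levels)),
                as.integer(n_gray_levels), d[1], d[2], as.integer(offset))
  glcm_stats_from_matrix(M)
}

glrlm_stats_from_matrix <- function(R) {
  nr <- sum(R)
  if (nr == 0) return(setNames(rep(NA_real_, length(GLRLM_STATS)), GLRLM_STATS))
  gi <- row(R); rj <- col(R)
  np <- sum(R * rj)  # voxels covered by runs
  c(SRE = sum(R / rj^2) / nr,
    LRE = sum(R * rj^2) / nr,
    GLN = sum(rowSums(R)^2) / nr,
    RLN = sum(colSums(R)^2) / nr,
    RP = nr / np,
    LGRE = sum(R / gi^2) / nr,
    HGRE = sum(R * gi^2) / nr,
    SRLGE = sum(R / (gi^2 * rj^2)) / nr,
    SRHGE = sum(R * gi^2 / rj^2) / nr,
    LRLGE = sum(R * rj^2 / gi^2) / nr,
    LRHGE = sum(R * gi^2 * rj^2) / nr)
}

#' GLRLM statistics (2.5D) for one run direction
#'
#' Runs of equal gray level are enumerated per axial slice along the
#' in-plane direction; out-of-mask voxels break runs. Matrices are
#' accumulated over slices before the 11 statistics are computed.
#'
#' @inheritParams glcm_features_25d
#' @return Named numeric vector of 11 statistics.
#' @export
glrlm_features_25d <- function(levels, direction,
                               n_gray_levels = max(levels)) {
  d <- direction_offset(direction)
  R <- cpp_glrlm(as.integer(levels), as.integer(dim(levels)),
                 as.integer(n_gray_levels), d[1], d[2])
  glrlm_stats_from_matrix(R)
}

ngtdm_stats_from_tables <- function(s, n, coarseness_cap = 1e6) {
  N <- sum(n)
  if (N == 0) return(setNames(rep(NA_real_, length(NGTDM_STATS)), NGTDM_STATS))
  G <- length(s)
  p <- n / N
  present <- which(p > 0)
  Ngl <- length(present)
  pi_ <- p[present]; si <- s[present]; gi <- present
  coars <- if (sum(p * s) > 0) 1 / sum(p * s) else coarseness_cap
  coars <- min(coars, coarseness_cap)
  if (Ngl > 1) {
    dif2 <- outer(gi, gi, function(a, b) (a - b)^2)
    contrast <- sum(outer(pi_, pi_) * dif2) / (Ngl * (Ngl - 1)) * sum(s) / N
    busy_den <- sum(abs(outer(gi * pi_, gi * pi_, "-")))
    busy <- if (busy_den > 0) sum(p * s) / busy_den else 0
    psum <- outer(pi_, pi_, "+")
    ps <- outer(pi_ * si, pi_ * si, "+")
    cmplx <- sum(abs(outer(gi, gi, "-")) * ps / (N * psum))
    strength_num <- sum(psum * dif2)
    strength <- if (sum(s) > 0) strength_num / sum(s) else 0
  } else {
    contrast <- 0; busy <- 0; cmplx <- 0; strength <- 0
  }
  c(Coarseness = coars, Contrast = contrast, Busyness = busy,
    Complexity = cmplx, Strength = strength)
}

#' NGTDM statistics (2.5D)
#'
#' Amadasun-King neighbourhood gray-tone difference features from in-slice
#' 8-neighbourhoods; voxels without any in-mask neighbour are excluded.
#' Coarseness of a perfectly homogeneous region is capped at `1e6`.
#'
#' @inheritParams glcm_features_25d
#' @return Named numeric vector: coarseness, contrast, busyness, complexity,
#'   strength.
#' @export
ngtdm_features_25d <- function(levels, n_gray_levels = max(levels)) {
  t <- cpp_ngtdm(as.integer(levels), as.integer(dim(levels)),
                 as.integer(n_gray_levels))
  ngtdm_stats_from_tables(t$s, t$n)
}
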