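#' Extract the full 884-feature bank from one ROI
#'
#' Runs all seven feature families on the in-mask voxels. A degenerate ROI
#' (empty, flagged by the ROI builder, or below `min_voxels`) yields a
#' vector of 884 `NA`s so that downstream null handling sees every name.
#' Texture matrices are computed on the tight bounding box of the mask,
#' which leaves the values unchanged (translation invariance) but keeps the
#' cost proportional to the ROI.
#'
#' @param image numeric 3-D HU array (or an [rd_volume()]).
#' @param mask logical ROI mask.
#' @param spacing voxel spacing in mm (taken from `image` if it is an
#'   `rd_volume`).
#' @param cfg a [feature_bank_config()].
#' @return Named numeric vector of length 884.
#' @export
extract_features <- function(image, mask, spacing = NULL,
                             cfg = feature_bank_config()) {
  if (inherits(image, "rd_volume")) {
    spacing <- image$spacing
    image <- image$data
  }
  stopifnot(!is.null(spacing))
  nm <- feature_bank_names(cfg)
  degen <- isTRUE(attr(mask, "degenerate")) || sum(mask) < cfg$min_voxels
  if (degen) return(setNames(rep(NA_real_, length(nm)), nm))

  bb <- mask_bbox(mask, pad = 1)
  img <- crop_to_bbox(image, bb)
  msk <- crop_to_bbox(mask, bb)
  G <- cfg$n_gray_levels
  lev <- discretize(img, msk, G)

  goh <- intensity_histogram_features(img, msk)

  # opposite directions share the symmetrized matrix; compute each base
  # direction once and reuse for direction + 180
  dirs <- cfg$glcm_directions
  base <- dirs[dirs < 180]
  glcm_vals <- list()
  for (d in base) {
    for (o in cfg$glcm_offsets) {
      glcm_vals[[paste(d, o)]] <- glcm_features_25d(lev, d, o, G)
    }
  }
  glcm <- unlist(lapply(dirs, function(d) {
    b <- if (d >= 180) d - 180 else d
    unlist(lapply(cfg$glcm_offsets, function(o) glcm_vals[[paste(b, o)]]))
  }), use.names = FALSE)

  glrlm <- unlist(lapply(cfg$glrlm_directions, function(d)
    glrlm_features_25d(lev, d, G)), use.names = FALSE)

  idf <- intensity_direct_features(img, msk, cfg$local_window)
  ngtdm <- ngtdm_features_25d(lev, G)
  gf <- gaussfit_features(img, msk, cfg$gaussfit_components)
  shp <- shape_features(msk, spacing, cfg$hull_directions)

  out <- c(unname(goh), glcm, glrlm, unname(idf), unname(ngtdm),
           unname(gf), unname(shp))
  setNames(out, nm)
}

#' Extract features from all six ROIs of one patient
#'
#' @param patient an `rd_patient`.
#' @param masks named list of six ROI masks (from [build_rois()]).
#' @param cfg a [feature_bank_config()].
#' @return Named numeric vector of `6 * 884 = 5304` values; names are
#'   prefixed with the ROI label (e.g. `PTV_100PD_F2.GLCM250.1_Contrast`).
#' @export
extract_all <- function(patient, masks, cfg = feature_bank_config()) {
  out <- lapply(names(masks), function(lab) {
    v <- extract_features(patient$image, masks[[lab]], cfg = cfg)
    setNames(v, paste0(lab, "_", names(v)))
  })
  unlist(out)
}

#' Extract the radiomics feature table for a whole cohort
#'
#' Builds the six ROIs for every patient and extracts the full bank,
#' returning one row per patient.
#'
#' @param cohort an `rd_cohort`.
#' @param roi_cfg an [roi_config()].
#' @param bank_cfg a [feature_bank_config()].
#' @param verbose print progress every 25 patients.
#' @return data.frame of 5304 feature columns plus an `id` column.
#' @export
extract_cohort_features <- function(cohort, roi_cfg = roi_config(),
                                    bank_cfg = feature_bank_config(),
                                    verbose = FALSE) {
  rows <- vector("list", length(cohort$patients))
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    masks <- build_rois(p, roi_cfg)
    rows[[i]] <- extract_all(p, masks, bank_cfg)
    if (verbose && i %% 25 == 0)
      message(sprintf("extracted %d / %d patients", i, length(rows)))
  }
  ft <- as.data.frame(do.call(rbind, rows))
  cbind(id = vapply(cohort$patients, function(p) p$id, character(1)), ft,
        stringsAsFactors = FALSE)
}

# Compute one named feature on an image+mask (used by the sliding map).
extract_single_feature <- function(image, mask, spacing, name,
                                   cfg = feature_bank_config()) {
  fam <- sub("^F([0-9])\\..*$", "\\1", name)
  G <- cfg$n_gray_levels
  val <- switch(fam,
    "1" = intensity_histogram_features(image, mask)[sub("^F1\\.", "", name)],
    "2" = {
      p <- regmatches(name, regexec("GLCM25([0-9]+)\\.([0-9]+)_(.*)$", name))[[1]]
      lev <- discretize(image, mask, G)
      glcm_features_25d(lev, as.numeric(p[2]), as.numeric(p[3]), G)[p[4]]
    },
    "3" = {
      p <- regmatches(name, regexec("GLRLM25([0-9]+)_(.*)$", name))[[1]]
      lev <- discretize(image, mask, G)
      glrlm_features_25d(lev, as.numeric(p[2]), G)[p[3]]
    },
    "4" = intensity_direct_features(image, mask, cfg$local_window)[
      sub("^F4\\.", "", name)],
    "5" = {
      lev <- discretize(image, mask, G)
      ngtdm_features_25d(lev, G)[sub("^F5\\.NID25_", "", name)]
    },
    "6" = gaussfit_features(image, mask, cfg$gaussfit_components)[
      sub("^F6\\.", "", name)],
    "8" = shape_features(mask, spacing, cfg$hull_directions)[
      sub("^F8\\.", "", name)],
    stop("cannot parse feature name: ", name))
  unname(val)
}

#' Sliding sub-volume feature map
#'
#' Evaluates a named feature on the in-mask window (default 7x7x7 voxels)
#' centred at every in-mask voxel, producing a scalar volume for spatial
#' inspection of texture heterogeneity. Voxels outside the mask are `NA`.
#'
#' @param image numeric 3-D HU array or `rd_volume`.
#' @param mask logical ROI mask.
#' @param feature_name bank feature name without ROI prefix
#'   (e.g. `"F1.GOH_Mean"`).
#' @param window odd window edge length in voxels.
#' @param spacing voxel spacing (taken from the volume if given).
#' @param cfg a [feature_bank_config()].
#' @param stride evaluate every `stride`-th voxel along each axis (the rest
#'   stay `NA`); 1 evaluates everywhere.
#' @return Numeric array of the mask's shape.
#' @export
sliding_feature_map <- function(image, mask, feature_name, window = 7,
                                spacing = NULL, cfg = feature_bank_config(),
                                stride = 1) {
  if (inherits(image, "rd_volume")) {
    spacing <- image$spacing
    image <- image$data
  }
  stopifnot(window %% 2 == 1, !is.null(spacing))
  r <- (window - 1) / 2
  d <- dim(image)
  out <- array(NA_real_, dim = d)
  idx <- which(mask, arr.ind = TRUE)
  if (stride > 1) {
    keep <- rowSums((idx - 1) %% stride == 0) == 3
    idx <- idx[keep, , drop = FALSE]
  }
  for (t in seq_len(nrow(idx))) {
    v <- idx[t, ]
    rng <- lapply(1:3, function(a) max(1, v[a] - r):min(d[a], v[a] + r))
    wi <- image[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    wm <- mask[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    out[v[1], v[2], v[3]] <- extract_single_feature(wi, wm, spacing,
                                                    feature_name, cfg)
  }
  out
}
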