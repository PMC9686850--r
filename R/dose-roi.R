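#' ROI construction configuration
#'
#' Thresholds used to carve the six dose-gradient regions of interest: PTV
#' sub-volumes at fractions of the prescription and skin shells at absolute
#' isodose levels.
#'
#' @param prescription_Gy prescribed dose in Gy (> 0).
#' @param ptv_levels strictly increasing dose fractions for the PTV ROIs.
#' @param skin_levels_Gy strictly increasing absolute dose levels (Gy) for
#'   the skin ROIs.
#' @param min_voxels masks below this voxel count are flagged degenerate and
#'   yield null features downstream instead of failing.
#' @return An object of class `rd_roi_config`.
#' @export
roi_config <- function(prescription_Gy = 50,
                       ptv_levels = c(1.00, 1.05, 1.08),
                       skin_levels_Gy = c(20, 30, 40),
                       min_voxels = 27) {
  stopifnot(prescription_Gy > 0,
            all(diff(ptv_levels) > 0), all(diff(skin_levels_Gy) > 0))
  structure(list(prescription_Gy = prescription_Gy,
                 ptv_levels = ptv_levels,
                 skin_levels_Gy = skin_levels_Gy,
                 min_voxels = as.integer(min_voxels)),
            class = "rd_roi_config")
}

#' Resample a dose grid onto an image grid
#'
#' Trilinear interpolation in physical coordinates; target voxels outside the
#' dose grid's extent receive 0 Gy. Masks are never resampled — dose always
#' moves to the image grid.
#'
#' @param dose an [rd_volume()] of dose values (Gy).
#' @param target an [rd_volume()] defining the output grid.
#' @return An `rd_volume` of dose on the target grid.
#' @export
resample_dose <- function(dose, target) {
  stopifnot(inherits(dose, "rd_volume"), inherits(target, "rd_volume"))
  dd <- dim(dose$data); td <- dim(target$data)
  dose_hi <- dose$origin + (dd - 1) * dose$spacing
  targ_hi <- target$origin + (td - 1) * target$spacing
  if (any(target$origin > dose_hi) || any(targ_hi < dose$origin))
    stop("dose and target grids have disjoint physical extents")
  if (identical(dd, td) && isTRUE(all.equal(dose$spacing, target$spacing)) &&
      isTRUE(all.equal(dose$origin, target$origin)))
    return(rd_volume(dose$data, target$spacing, target$origin))

  ax <- lapply(1:3, function(a)
    target$origin[a] + (seq_len(td[a]) - 1) * target$spacing[a])
  # continuous (1-based) index of every target voxel centre in the dose grid
  gx <- (rep(ax[[1]], times = td[2] * td[3]) - dose$origin[1]) / dose$spacing[1] + 1
  gy <- (rep(rep(ax[[2]], each = td[1]), times = td[3]) - dose$origin[2]) / dose$spacing[2] + 1
  gz <- (rep(ax[[3]], each = td[1] * td[2]) - dose$origin[3]) / dose$spacing[3] + 1

  inside <- gx >= 1 & gx <= dd[1] & gy >= 1 & gy <= dd[2] & gz >= 1 & gz <= dd[3]
  out <- numeric(prod(td))
  if (any(inside)) {
    x <- gx[inside]; y <- gy[inside]; z <- gz[inside]
    x0 <- pmin(floor(x), dd[1] - 1); y0 <- pmin(floor(y), dd[2] - 1)
    z0 <- pmin(floor(z), dd[3] - 1)
    if (dd[1] == 1) x0 <- rep(1, length(x))
    if (dd[2] == 1) y0 <- rep(1, length(y))
    if (dd[3] == 1) z0 <- rep(1, length(z))
    fx <- x - x0; fy <- y - y0; fz <- z - z0
    at <- function(i, j, k) dose$data[cbind(i, j, k)]
    x1 <- pmin(x0 + 1, dd[1]); y1 <- pmin(y0 + 1, dd[2]); z1 <- pmin(z0 + 1, dd[3])
    v <- (1 - fx) * (1 - fy) * (1 - fz) * at(x0, y0, z0) +
         fx * (1 - fy) * (1 - fz) * at(x1, y0, z0) +
         (1 - fx) * fy * (1 - fz) * at(x0, y1, z0) +
         fx * fy * (1 - fz) * at(x1, y1, z0) +
         (1 - fx) * (1 - fy) * fz * at(x0, y0, z1) +
         fx * (1 - fy) * fz * at(x1, y0, z1) +
         (1 - fx) * fy * fz * at(x0, y1, z1) +
         fx * fy * fz * at(x1, y1, z1)
    out[inside] <- v
  }
  rd_volume(array(out, dim = td), target$spacing, target$origin)
}

threshold_roi <- function(dose_arr, mask, level, label, min_voxels) {
  m <- mask & (dose_arr >= level)
  attr(m, "label") <- label
  attr(m, "degenerate") <- sum(m) < min_voxels
  m
}

#' Build the three PTV dose-gradient ROIs
#'
#' `PTV_100PD`, `PTV_105PD` and `PTV_108PD`: the intersections of the PTV
#' mask with the regions receiving at least 100%, 105% and 108% of the
#' prescription. Thresholds are inclusive (`dose >= level`).
#'
#' @param dose `rd_volume` of dose resampled onto the image grid.
#' @param ptv_mask logical array on the image grid.
#' @param cfg an [roi_config()].
#' @return Named list of three logical masks, each carrying `label` and
#'   `degenerate` attributes (degenerate = fewer than `min_voxels` voxels).
#' @export
build_ptv_rois <- function(dose, ptv_mask, cfg = roi_config()) {
  if (!any(ptv_mask)) stop("empty PTV mask")
  stopifnot(identical(dim(dose$data), dim(ptv_mask)))
  labs <- sprintf("PTV_%dPD", round(cfg$ptv_levels * 100))
  out <- lapply(seq_along(cfg$ptv_levels), function(i)
    threshold_roi(dose$data, ptv_mask, cfg$ptv_levels[i] * cfg$prescription_Gy,
                  labs[i], cfg$min_voxels))
  names(out) <- labs
  out
}

#' Build the three skin isodose ROIs
#'
#' `SKIN_20Gy`, `SKIN_30Gy`, `SKIN_40Gy`: skin voxels receiving at least the
#' absolute threshold dose (inclusive).
#'
#' @inheritParams build_ptv_rois
#' @param skin_mask logical array on the image grid.
#' @return Named list of three logical masks with `label`/`degenerate`
#'   attributes.
#' @export
build_skin_rois <- function(dose, skin_mask, cfg = roi_config()) {
  if (!any(skin_mask)) stop("empty skin mask")
  stopifnot(identical(dim(dose$data), dim(skin_mask)))
  labs <- sprintf("SKIN_%dGy", round(cfg$skin_levels_Gy))
  out <- lapply(seq_along(cfg$skin_levels_Gy), function(i)
    threshold_roi(dose$data, skin_mask, cfg$skin_levels_Gy[i],
                  labs[i], cfg$min_voxels))
  names(out) <- labs
  out
}

#' Build all six ROIs for one patient
#'
#' Resamples the dose onto the image grid and applies [build_ptv_rois()] and
#' [build_skin_rois()].
#'
#' @param patient an `rd_patient`.
#' @param cfg an [roi_config()].
#' @return Named list of six logical masks in the order PTV_100PD, PTV_105PD,
#'   PTV_108PD, SKIN_20Gy, SKIN_30Gy, SKIN_40Gy.
#' @export
build_rois <- function(patient, cfg = roi_config()) {
  dose <- resample_dose(patient$dose, patient$image)
  c(build_ptv_rois(dose, patient$ptv_mask, cfg),
    build_skin_rois(dose, patient$skin_mask, cfg))
}

#' Summarise ROI sizes
#'
#' @param rois named list of ROI masks.
#' @param spacing voxel spacing in mm.
#' @return data.frame with voxel counts and volumes in cc.
#' @export
roi_summary <- function(rois, spacing) {
  data.frame(
    roi = names(rois),
    voxels = vapply(rois, sum, numeric(1)),
    volume_cc = vapply(rois, function(m) sum(m) * voxel_volume_cc(spacing),
                       numeric(1)),
    degenerate = vapply(rois, function(m) isTRUE(attr(m, "degenerate")),
                        logical(1)),
    row.names = NULL
  )
}
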