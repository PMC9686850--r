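#' Scalar image volume on a regular grid
#'
#' Container for a 3-D scalar array (CT in Hounsfield units, dose in Gy)
#' with voxel spacing and origin metadata. Voxel centre `(i, j, k)` sits at
#' physical position `origin + (c(i, j, k) - 1) * spacing` (mm).
#'
#' @param data numeric 3-D array.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param origin numeric length-3 physical position of voxel (1,1,1), mm.
#' @return An object of class `rd_volume`.
#' @export
rd_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3,
            length(spacing) == 3, all(spacing > 0), length(origin) == 3)
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "rd_volume")
}

#' @export
print.rd_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<rd_volume> %d x %d x %d voxels, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], paste(x$spacing, collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.rd_volume <- function(x) dim(x$data)

voxel_volume_cc <- function(spacing) prod(spacing) / 1000

# Physical coordinates (mm) of voxel centres of the in-mask voxels,
# n x 3 matrix in column-major voxel order.
mask_coords <- function(mask, spacing, origin = c(0, 0, 0)) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}

# Tight bounding box of a mask with `pad` voxels of margin, clipped to the
# grid. Returns index vectors per axis.
mask_bbox <- function(mask, pad = 0) {
  stopifnot(any(mask))
  idx <- which(mask, arr.ind = TRUE)
  d <- dim(mask)
  lapply(1:3, function(a) {
    lo <- max(1L, min(idx[, a]) - pad)
    hi <- min(d[a], max(idx[, a]) + pad)
    lo:hi
  })
}

crop_to_bbox <- function(arr, bb) arr[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]

# Morphological erosion of a binary mask by a physical radius (mm): a voxel
# survives when every voxel centre within `r_mm` lies inside the mask.
erode_mask <- function(mask, spacing, r_mm) {
  d <- dim(mask)
  steps <- lapply(1:3, function(a) {
    k <- floor(r_mm / spacing[a])
    -k:k
  })
  out <- mask
  for (dx in steps[[1]]) for (dy in steps[[2]]) for (dz in steps[[3]]) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (sqrt(sum((c(dx, dy, dz) * spacing)^2)) > r_mm) next
    sh <- shift_array(mask, c(dx, dy, dz), fill = FALSE)
    out <- out & sh
  }
  out
}

# Shift an array by an integer voxel offset, filling exposed cells.
shift_array <- function(arr, off, fill = FALSE) {
  d <- dim(arr)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    if (abs(o) >= d[a]) return(out)
    if (o >= 0) {
      dst[[a]] <- (1 + o):d[a]; src[[a]] <- 1:(d[a] - o)
    } else {
      dst[[a]] <- 1:(d[a] + o); src[[a]] <- (1 - o):d[a]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# Gaussian smoothing of a 3-D array; sigma_mm is converted to voxels.
smooth_volume <- function(arr, spacing, sigma_mm, mode = c("zero", "replicate")) {
  mode <- match.arg(mode)
  sig <- sigma_mm / spacing
  out <- cpp_smooth3(as.numeric(arr), as.integer(dim(arr)), as.numeric(sig),
                     if (mode == "zero") 0L else 1L)
  array(out, dim = dim(arr))
}
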