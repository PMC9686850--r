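vol <- function(arr, sp = c(1, 1, 1), or = c(0, 0, 0))
  rd_volume(arr, sp, or)

test_that("resampling is the identity on matching grids and preserves constants", {
  a <- array(runif(4 * 4 * 3, 0, 60), dim = c(4, 4, 3))
  d <- vol(a)
  expect_equal(resample_dose(d, d)$data, a)

  u <- vol(array(50, dim = c(6, 6, 4)), sp = c(2, 2, 2))
  tgt <- vol(array(0, dim = c(11, 11, 7)), sp = c(1, 1, 1))
  out <- resample_dose(u, tgt)
  expect_true(all(abs(out$data - 50) < 1e-12))
})

test_that("trilinear resampling reproduces a linear ramp analytically", {
  # dose = 2x + 3y + 5z (mm) is reproduced exactly by trilinear interpolation
  d <- c(9, 9, 5); sp <- c(2, 2, 4)
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  ramp <- outer(outer(2 * xs, 3 * ys, "+"), 5 * zs, "+")
  dose <- vol(ramp, sp)
  tgt <- vol(array(0, dim = c(17, 17, 9)), sp = c(1, 1, 2))
  out <- resample_dose(dose, tgt)
  xt <- (seq_len(17) - 1) * 1; yt <- xt; zt <- (seq_len(9) - 1) * 2
  expected <- outer(outer(2 * xt, 3 * yt, "+"), 5 * zt, "+")
  expect_lt(max(abs(out$data - expected)), 1e-9)
})

test_that("disjoint extents are rejected", {
  a <- vol(array(1, dim = c(4, 4, 4)))
  b <- vol(array(1, dim = c(4, 4, 4)), or = c(100, 100, 100))
  expect_error(resample_dose(a, b), "disjoint")
})

test_that("PTV thresholds behave as inclusive cuts", {
  cfg <- roi_config(prescription_Gy = 50, min_voxels = 1)
  ptv <- array(FALSE, dim = c(6, 6, 3)); ptv[2:5, 2:5, ] <- TRUE
  dose <- vol(array(1.06 * 50, dim = c(6, 6, 3)))
  rois <- build_ptv_rois(dose, ptv, cfg)
  expect_equal(rois$PTV_100PD, ptv, ignore_attr = TRUE)
  expect_equal(rois$PTV_105PD, ptv, ignore_attr = TRUE)
  expect_equal(sum(rois$PTV_108PD), 0)
})

test_that("skin thresholds behave as inclusive absolute cuts", {
  cfg <- roi_config(min_voxels = 1)
  skin <- array(FALSE, dim = c(6, 6, 3)); skin[, c(1, 6), ] <- TRUE
  dose <- vol(array(25, dim = c(6, 6, 3)))
  rois <- build_skin_rois(dose, skin, cfg)
  expect_equal(rois$SKIN_20Gy, skin, ignore_attr = TRUE)
  expect_equal(sum(rois$SKIN_30Gy), 0)
  expect_equal(sum(rois$SKIN_40Gy), 0)
})

test_that("toy-grid masks match voxel-by-voxel enumeration", {
  dose_vals <- c(48, 50, 52.5, 54, 55, 49.9, 50.0, 53.99, 54.0, 56, 40, 20,
                 30, 44.4, 50.1, 60)
  dose <- vol(array(dose_vals, dim = c(4, 4, 1)))
  mask <- array(TRUE, dim = c(4, 4, 1))
  cfg <- roi_config(prescription_Gy = 50, min_voxels = 1)
  rois <- build_ptv_rois(dose, mask, cfg)
  expect_equal(as.vector(rois$PTV_100PD), dose_vals >= 50)
  expect_equal(as.vector(rois$PTV_105PD), dose_vals >= 52.5)
  expect_equal(as.vector(rois$PTV_108PD), dose_vals >= 54)
  srois <- build_skin_rois(dose, mask, cfg)
  expect_equal(as.vector(srois$SKIN_20Gy), dose_vals >= 20)
  expect_equal(as.vector(srois$SKIN_40Gy), dose_vals >= 40)
})

test_that("thresholding is idempotent and monotone in the level", {
  set.seed(7)
  dose <- vol(array(runif(8^3, 0, 60), dim = c(8, 8, 8)))
  mask <- array(runif(8^3) < 0.7, dim = c(8, 8, 8))
  cfg <- roi_config(min_voxels = 1)
  r1 <- build_ptv_rois(dose, mask, cfg)
  expect_true(all(r1$PTV_100PD >= r1$PTV_105PD))
  expect_true(all(r1$PTV_105PD >= r1$PTV_108PD))
  # idempotence: applying the same threshold to an already-thresholded mask
  r2 <- build_ptv_rois(dose, r1$PTV_100PD & TRUE, cfg)
  expect_equal(sum(r2$PTV_100PD), sum(r1$PTV_100PD))
})

test_that("empty and degenerate masks are handled", {
  dose <- vol(array(55, dim = c(4, 4, 2)))
  expect_error(build_ptv_rois(dose, array(FALSE, dim = c(4, 4, 2))), "empty")
  small <- array(FALSE, dim = c(4, 4, 2)); small[1, 1, 1] <- TRUE
  rois <- build_ptv_rois(dose, small, roi_config(min_voxels = 27))
  expect_true(attr(rois$PTV_100PD, "degenerate"))
})

test_that("phantom ROIs nest and report volumes in cc", {
  co <- tiny_cohort(n = 10, pos = 6, seed = 9)
  p <- co$patients[[1]]
  rois <- build_rois(p)
  expect_true(all(rois$PTV_100PD >= rois$PTV_105PD))
  expect_true(all(rois$PTV_105PD >= rois$PTV_108PD))
  expect_true(all(rois$SKIN_20Gy >= rois$SKIN_30Gy))
  expect_true(all(rois$SKIN_30Gy >= rois$SKIN_40Gy))
  s <- roi_summary(rois, p$image$spacing)
  expect_equal(s$volume_cc, s$voxels * prod(p$image$spacing) / 1000)
})
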