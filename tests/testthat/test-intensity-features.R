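test_that("discretization maps extremes to extremes and ramps to uniform bins", {
  img <- array(0, dim = c(4, 4, 1)); msk <- array(TRUE, dim = c(4, 4, 1))
  expect_true(all(discretize(img, msk, 64)[msk] == 1L))

  img2 <- array(c(0, 100, rep(0, 14)), dim = c(4, 4, 1))
  lev2 <- discretize(img2, msk, 64)
  expect_equal(sort(unique(lev2[msk])), c(1L, 64L))

  # uniform ramp: bin occupation deviates by at most one
  img3 <- array(seq(0, 1, length.out = 128), dim = c(8, 8, 2))
  msk3 <- array(TRUE, dim = c(8, 8, 2))
  counts <- tabulate(discretize(img3, msk3, 64)[msk3], 64)
  expect_lte(diff(range(counts)), 1)
})

test_that("intensity direct features: degenerate and two-voxel cases", {
  img <- array(7, dim = c(3, 3, 3)); msk <- array(TRUE, dim = c(3, 3, 3))
  f <- intensity_direct_features(img, msk)
  expect_equal(unname(f["ID_Range"]), 0)
  expect_equal(unname(f["ID_LocalStdMedian"]), 0)

  img2 <- array(0, dim = c(2, 1, 1)); img2[] <- c(-10, 30)
  msk2 <- array(TRUE, dim = c(2, 1, 1))
  f2 <- intensity_direct_features(img2, msk2)
  expect_equal(unname(f2["ID_Range"]), 40)
  expect_equal(unname(f2["ID_Mean"]), 10)
})

test_that("local-window aggregates match a brute-force sliding oracle", {
  set.seed(21)
  d <- c(6, 6, 3)
  img <- array(rnorm(prod(d), 40, 12), dim = d)
  msk <- array(runif(prod(d)) < 0.85, dim = d)
  msk[2, 3, 2] <- TRUE
  f <- intensity_direct_features(img, msk, local_window = 1)
  # brute force per-voxel window ranges
  idx <- which(msk, arr.ind = TRUE)
  rng <- apply(idx, 1, function(v) {
    w <- expand.grid(x = max(1, v[1] - 1):min(d[1], v[1] + 1),
                     y = max(1, v[2] - 1):min(d[2], v[2] + 1),
                     z = max(1, v[3] - 1):min(d[3], v[3] + 1))
    vals <- img[as.matrix(w)][msk[as.matrix(w)]]
    diff(range(vals))
  })
  expect_equal(unname(f["ID_LocalRangeMax"]), max(rng))
  expect_equal(unname(f["ID_LocalRangeMin"]), min(rng))
  expect_equal(unname(f["ID_LocalRangeMean"]), mean(rng))
})

test_that("histogram features: symmetry, quantile rule and MAD", {
  set.seed(5)
  x <- rnorm(1e4)
  x <- c(x, -x)  # exactly symmetric
  img <- array(x, dim = c(100, 100, 2)); msk <- array(TRUE, dim = dim(img))
  f <- intensity_histogram_features(img, msk)
  expect_equal(unname(f["GOH_Mean"]), unname(f["GOH_Median"]), tolerance = 1e-9)
  expect_lt(abs(f["GOH_Skewness"]), 1e-9)

  img2 <- array(as.numeric(1:1000), dim = c(10, 10, 10))
  msk2 <- array(TRUE, dim = dim(img2))
  f2 <- intensity_histogram_features(img2, msk2)
  expect_equal(unname(f2["GOH0.975Quantile"]),
               unname(quantile(1:1000, 0.975, type = 7)))
  expect_equal(unname(f2["GOH0.025Quantile"]),
               unname(quantile(1:1000, 0.025, type = 7)))

  img3 <- array(3.5, dim = c(4, 4, 4)); msk3 <- array(TRUE, dim = dim(img3))
  expect_equal(unname(intensity_histogram_features(img3, msk3)["GOH_MAD"]), 0)
})

test_that("Gaussian-fit features recover simulated mixtures", {
  set.seed(8)
  x <- rnorm(5000, 40, 8)
  img <- array(x, dim = c(50, 50, 2)); msk <- array(TRUE, dim = dim(img))
  f <- gaussfit_features(img, msk, components = 1)
  expect_lt(abs(f["IHGaussFit1GaussMean"] - 40), 1)
  expect_lt(abs(f["IHGaussFit1GaussStd"] - 8), 1)

  # constant data: zero std, unit mass amplitude
  imgc <- array(12, dim = c(5, 5, 4)); mskc <- array(TRUE, dim = dim(imgc))
  fc <- gaussfit_features(imgc, mskc, components = 1)
  expect_equal(unname(fc["IHGaussFit1GaussStd"]), 0)

  # bimodal mixture at 0 and 100: two-component means straddle 50
  set.seed(9)
  xb <- c(rnorm(3000, 0, 6), rnorm(3000, 100, 6))
  imgb <- array(xb, dim = c(60, 50, 2)); mskb <- array(TRUE, dim = dim(imgb))
  fb <- gaussfit_features(imgb, mskb, components = 2)
  expect_lt(fb["IHGaussFit2Gauss1Mean"], 50)
  expect_gt(fb["IHGaussFit2Gauss2Mean"], 50)
})

test_that("shape features: single voxel, two objects and a digitized ball", {
  m <- array(FALSE, dim = c(5, 5, 5)); m[3, 3, 3] <- TRUE
  f <- shape_features(m, c(1, 1, 1))
  expect_equal(unname(f["ShapeVolume"]), 1)
  expect_equal(unname(f["ShapeNumberOfObjects"]), 1)

  m2 <- array(FALSE, dim = c(10, 6, 4))
  m2[1:3, 1:3, 1:2] <- TRUE
  m2[7:9, 4:6, 3:4] <- TRUE
  expect_equal(unname(shape_features(m2, c(1, 1, 1))["ShapeNumberOfObjects"]), 2)

  d <- c(31, 31, 31); cc <- 16
  coords <- expand.grid(x = 1:31, y = 1:31, z = 1:31)
  ball <- array((coords$x - cc)^2 + (coords$y - cc)^2 + (coords$z - cc)^2 <= 100,
                dim = d)
  fb <- shape_features(ball, c(1, 1, 1))
  expect_gte(unname(fb["ShapeSphericity"]), 0.9)
  expect_lte(unname(fb["ShapeSphericity"]), 1.0)
  expect_lt(abs(fb["ShapeMeanBreadth"] - 20) / 20, 0.10)
})
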