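symmetrize <- function(M) { S <- M + t(M); S / sum(S) }

test_that("GLCM matrices match brute-force enumeration exactly on toy volumes", {
  for (seed in c(1, 2, 3)) {
    lev <- toy_levels(c(8, 8, 3), G = 5, seed = seed)
    for (dir in c(0, 45, 90, 135)) {
      for (off in c(1, 2)) {
        M <- dermrad:::cpp_glcm(as.integer(lev), dim(lev), 5L,
                                oracle_dir(dir)[1], oracle_dir(dir)[2],
                                as.integer(off))
        expect_equal(unclass(M), oracle_glcm_counts(lev, oracle_dir(dir), off),
                     ignore_attr = TRUE)
      }
    }
  }
})

test_that("GLCM statistics on a constant region are degenerate as expected", {
  lev <- array(0L, dim = c(5, 5, 2)); lev[2:4, 2:4, ] <- 1L
  st <- glcm_features_25d(lev, 0, 1, n_gray_levels = 4)
  expect_equal(unname(st["Contrast"]), 0)
  expect_equal(unname(st["Energy"]), 1)
  expect_equal(unname(st["Dissimilarity"]), 0)
})

test_that("a two-level checkerboard has horizontal GLCM contrast 1", {
  lev <- array(0L, dim = c(4, 4, 1))
  lev[, , 1] <- (outer(1:4, 1:4, "+") %% 2) + 1L
  st <- glcm_features_25d(lev, 0, 1, n_gray_levels = 2)
  expect_equal(unname(st["Contrast"]), 1)
})

test_that("opposite GLCM directions give identical statistics", {
  lev <- toy_levels(c(7, 6, 2), G = 4, seed = 11)
  for (d in c(0, 45, 90, 135)) {
    expect_equal(glcm_features_25d(lev, d, 1, 4),
                 glcm_features_25d(lev, d + 180, 1, 4))
  }
})

test_that("offsets exceeding the ROI extent give nulls", {
  lev <- array(0L, dim = c(3, 3, 1)); lev[2, 2, 1] <- 1L
  st <- glcm_features_25d(lev, 0, 5, n_gray_levels = 2)
  expect_true(all(is.na(st)))
})

test_that("GLRLM matrices match brute-force run listing", {
  # printed 5x5 example, hand-checkable
  sl <- matrix(c(1, 1, 2, 2, 2,
                 3, 1, 1, 2, 2,
                 3, 3, 1, 1, 1,
                 2, 2, 2, 3, 3,
                 1, 2, 3, 3, 3), 5, 5, byrow = TRUE)
  lev <- array(as.integer(sl), dim = c(5, 5, 1))
  for (dir in c(0, 45, 90, 135)) {
    M <- dermrad:::cpp_glrlm(as.integer(lev), dim(lev), 3L,
                             oracle_dir(dir)[1], oracle_dir(dir)[2])
    O <- oracle_glrlm_counts(lev, oracle_dir(dir))
    expect_equal(unclass(M)[, seq_len(ncol(O))], O, ignore_attr = TRUE)
  }
  # and random masked toys
  for (seed in 4:6) {
    lev <- toy_levels(c(8, 7, 3), G = 4, seed = seed)
    for (dir in c(0, 45, 90, 135)) {
      M <- dermrad:::cpp_glrlm(as.integer(lev), dim(lev), 4L,
                               oracle_dir(dir)[1], oracle_dir(dir)[2])
      O <- oracle_glrlm_counts(lev, oracle_dir(dir))
      expect_equal(unclass(M)[, seq_len(ncol(O))], O, ignore_attr = TRUE)
    }
  }
})

test_that("GLRLM statistics on degenerate rows have closed forms", {
  # constant 1xN row: a single run of length N, run percentage 1/N
  lev <- array(0L, dim = c(6, 1, 1)); lev[, 1, 1] <- 2L
  st <- glrlm_features_25d(lev, 0, n_gray_levels = 3)
  expect_equal(unname(st["RP"]), 1 / 6)
  expect_equal(unname(st["LRE"]), 36)
  # alternating levels: all runs length 1, SRE = 1
  lev2 <- array(0L, dim = c(6, 1, 1)); lev2[, 1, 1] <- rep(c(1L, 2L), 3)
  st2 <- glrlm_features_25d(lev2, 0, n_gray_levels = 2)
  expect_equal(unname(st2["SRE"]), 1)
  expect_equal(unname(st2["RP"]), 1)
})

test_that("NGTDM tables match hand computation", {
  # 3x3 slice, bright centre: s(bright) = |5 - mean(8 neighbours)|
  sl <- matrix(1L, 3, 3); sl[2, 2] <- 5L
  lev <- array(sl, dim = c(3, 3, 1))
  t <- dermrad:::cpp_ngtdm(as.integer(lev), dim(lev), 5L)
  expect_equal(t$s[5], abs(5 - 1))
  # each border 1-voxel sees the centre in its neighbourhood
  O <- oracle_ngtdm_tables(lev)
  expect_equal(as.numeric(t$s), O$s)
  expect_equal(as.numeric(t$n), O$n)
  # random toys
  for (seed in 7:9) {
    lev <- toy_levels(c(8, 8, 3), G = 5, seed = seed)
    t <- dermrad:::cpp_ngtdm(as.integer(lev), dim(lev), 5L)
    O <- oracle_ngtdm_tables(lev)
    expect_equal(as.numeric(t$s), O$s)
    expect_equal(as.numeric(t$n), O$n)
  }
})

test_that("NGTDM statistics: constant region and relabelling invariance", {
  lev <- array(0L, dim = c(5, 5, 2)); lev[2:4, 2:4, ] <- 3L
  st <- ngtdm_features_25d(lev, n_gray_levels = 4)
  expect_equal(unname(st["Contrast"]), 0)
  expect_equal(unname(st["Coarseness"]), 1e6)
  # identity relabelling leaves features unchanged
  lev2 <- toy_levels(c(6, 6, 2), G = 4, seed = 10)
  expect_equal(ngtdm_features_25d(lev2, 4), ngtdm_features_25d(lev2, 4))
})
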