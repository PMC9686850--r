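test_that("SMOTE reproduces the canonical 144/70 -> 280/140 balance", {
  set.seed(1)
  n_maj <- 144; n_min <- 70
  X <- rbind(matrix(rnorm(n_maj * 5, 0), ncol = 5),
             matrix(rnorm(n_min * 5, 2), ncol = 5))
  colnames(X) <- paste0("f", 1:5)
  y <- c(rep(1, n_maj), rep(0, n_min))
  out <- smote(X, y, smote_config(seed = 3))
  # classic doubling: 70 minority rows spawn 70 synthetics (140 minority
  # total); the 144 majority rows are untouched
  expect_equal(sum(out$y == 0), 140)
  expect_equal(sum(out$y == 1), 144)
  expect_equal(length(out$y), 284)
  # originals preserved, majority untouched
  expect_equal(out$X[1:214, ], X, ignore_attr = TRUE)
  expect_equal(sum(out$synthetic), 70)
})

test_that("synthetic rows lie on segments between original minority rows", {
  set.seed(2)
  X <- matrix(rnorm(60 * 3), ncol = 3)
  y <- c(rep(1, 40), rep(0, 20))
  out <- smote(X, y, smote_config(seed = 9))
  minors <- X[y == 0, , drop = FALSE]
  syn <- out$X[out$synthetic, , drop = FALSE]
  for (i in seq_len(nrow(syn))) {
    s <- syn[i, ]
    on_segment <- FALSE
    for (a in seq_len(nrow(minors))) {
      for (b in seq_len(nrow(minors))) {
        if (a == b) next
        d <- minors[b, ] - minors[a, ]
        t <- sum((s - minors[a, ]) * d) / sum(d * d)
        if (t >= -1e-9 && t <= 1 + 1e-9 &&
            sqrt(sum((minors[a, ] + t * d - s)^2)) < 1e-8) {
          on_segment <- TRUE
          break
        }
      }
      if (on_segment) break
    }
    expect_true(on_segment)
  }
})

test_that("SMOTE is deterministic under seed and clamps k with a warning", {
  set.seed(4)
  X <- matrix(rnorm(30 * 2), ncol = 2)
  y <- c(rep(1, 26), rep(0, 4))
  a <- suppressWarnings(smote(X, y, smote_config(seed = 5)))
  b <- suppressWarnings(smote(X, y, smote_config(seed = 5)))
  expect_identical(a$X, b$X)
  expect_warning(smote(X, y, smote_config(k_neighbors = 10, seed = 5)),
                 "clamped")
})

test_that("null-feature dropping removes exactly the affected columns", {
  ft <- data.frame(id = c("a", "b"),
                   PTV_100PD_F1.x = c(1, 2),
                   PTV_100PD_F1.y = c(1, NA),
                   SKIN_40Gy_F1.x = c(NA, NA),
                   SKIN_40Gy_F1.y = c(3, 4))
  out <- drop_null_features(ft)
  expect_equal(setdiff(names(out$features), "id"),
               c("PTV_100PD_F1.x", "SKIN_40Gy_F1.y"))
  rep <- out$report
  expect_equal(rep$retained[rep$roi == "PTV_100PD"], 1)
  expect_equal(rep$retained[rep$roi == "SKIN_40Gy"], 1)

  # no nulls: everything retained
  ft2 <- ft; ft2$PTV_100PD_F1.y <- c(1, 1); ft2$SKIN_40Gy_F1.x <- c(0, 0)
  expect_equal(ncol(drop_null_features(ft2)$features), ncol(ft2))
})

test_that("a patient-level degenerate ROI removes that ROI's whole bank", {
  nm <- feature_bank_names()
  good <- matrix(rnorm(3 * 884), nrow = 3,
                 dimnames = list(NULL, paste0("PTV_100PD_", nm)))
  bad <- matrix(rnorm(3 * 884), nrow = 3,
                dimnames = list(NULL, paste0("SKIN_40Gy_", nm)))
  bad[2, ] <- NA  # one patient's degenerate SKIN_40Gy
  out <- drop_null_features(as.data.frame(cbind(good, bad)))
  rep <- out$report
  expect_equal(rep$retained[rep$roi == "SKIN_40Gy"], 0)
  expect_equal(rep$retained[rep$roi == "PTV_100PD"], 884)
})

test_that("imputation leaves complete tables unchanged and is idempotent", {
  co <- tiny_cohort(n = 12, pos = 8, seed = 20, grid = c(16, 16, 16))
  cl <- co$clinical
  out <- impute_clinical(cl)
  expect_identical(out, cl)
})

test_that("continuous imputation beats the marginal SD on MVN data", {
  set.seed(11)
  n <- 300
  z <- matrix(rnorm(n * 3), ncol = 3)
  S <- matrix(c(1, .8, .6, .8, 1, .7, .6, .7, 1), 3)
  X <- z %*% chol(S)
  df <- as.data.frame(X)
  names(df) <- c("a", "b", "c")
  truth <- df
  holes <- cbind(sample(n, 40), sample(3, 40, replace = TRUE))
  for (i in seq_len(nrow(holes))) df[holes[i, 1], holes[i, 2]] <- NA
  imp <- impute_clinical(df)
  err <- vapply(seq_len(nrow(holes)), function(i)
    imp[holes[i, 1], holes[i, 2]] - truth[holes[i, 1], holes[i, 2]],
    numeric(1))
  expect_lt(sqrt(mean(err^2)), 1)         # below the unit marginal SD
  # observed cells never altered
  obs <- !is.na(df)
  expect_equal(as.matrix(imp)[as.matrix(obs)], as.matrix(truth)[as.matrix(obs)])
})

test_that("a single null in a collinear column is recovered exactly", {
  set.seed(12)
  a <- rnorm(50)
  df <- data.frame(a = a, b = 2 * a + 1, c = rnorm(50))
  df$b[17] <- NA
  imp <- impute_clinical(df)
  expect_lt(abs(imp$b[17] - (2 * a[17] + 1)), 1e-6)
})

test_that("categorical imputation fills with plausible levels", {
  set.seed(13)
  n <- 120
  x <- rnorm(n)
  g <- factor(ifelse(x > 0, "hi", "lo"))
  df <- data.frame(x = x, g = g)
  df$g[sample(n, 15)] <- NA
  imp <- impute_clinical(df, seed = 2)
  expect_false(anyNA(imp$g))
  # strongly predictable: imputed level should usually match the sign rule
  filled <- which(is.na(df$g))
  acc <- mean(imp$g[filled] == ifelse(x[filled] > 0, "hi", "lo"))
  expect_gt(acc, 0.8)
})

test_that("all-null and over-null columns are rejected with names", {
  df <- data.frame(a = c(NA, NA, NA), b = 1:3)
  expect_error(impute_clinical(df), "a")
})
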