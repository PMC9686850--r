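test_that("MWU filter matches wilcox.test and drops constants", {
  set.seed(1)
  X <- cbind(sig = c(rnorm(30, 1), rnorm(30)), noise = rnorm(60),
             const = rep(2, 60))
  y <- rep(c(1, 0), each = 30)
  out <- mwu_filter(X, y, alpha = 0.05)
  ref <- wilcox.test(X[y == 1, "sig"], X[y == 0, "sig"],
                     exact = FALSE, correct = TRUE)$p.value
  expect_equal(unname(out$p["sig"]), ref, tolerance = 1e-12)
  expect_true("sig" %in% out$retained)
  expect_false("const" %in% out$retained)
  expect_equal(unname(out$p["const"]), 1)
})

test_that("MWU normal approximation is close to the exact permutation law", {
  # n1 = n2 = 4: enumerate all 70 group assignments
  x <- c(1.2, 3.4, 2.2, 5.1, 0.3, 0.9, 1.7, 2.9)
  y <- rep(c(1, 0), each = 4)
  obs_u <- sum(rank(x)[y == 1]) - 4 * 5 / 2
  combos <- combn(8, 4)
  us <- apply(combos, 2, function(g) sum(rank(x)[g]) - 10)
  exact_p <- mean(abs(us - 8) >= abs(obs_u - 8))
  approx_p <- unname(mwu_filter(matrix(x, ncol = 1,
                                       dimnames = list(NULL, "f")),
                                y, alpha = 1)$p["f"])
  expect_lt(abs(approx_p - exact_p), 0.02)
})

test_that("U/(n1 n2) from the filter equals the AUC of the feature", {
  set.seed(2)
  x <- rnorm(50); y <- rbinom(50, 1, 0.5)
  y[1:2] <- c(0, 1)
  out <- mwu_filter(matrix(x, ncol = 1, dimnames = list(NULL, "f")), y, 1)
  expect_equal(unname(out$auc["f"]), auc(x, y), tolerance = 1e-12)
})

test_that("variance filter uses the min-max scale with closed forms", {
  X <- cbind(const = rep(5, 100),
             bin = rep(c(0, 1), 50),
             narrow = seq(0, 1, length.out = 100))
  out <- variance_filter(X, threshold = 0.05)
  expect_equal(unname(out$variance["const"]), 0)
  expect_equal(unname(out$variance["bin"]), 0.25)
  expect_true("bin" %in% out$retained)
  expect_false("const" %in% out$retained)
  out0 <- variance_filter(X, threshold = 0)
  expect_equal(sort(out0$retained), c("bin", "narrow"))
})

test_that("correlation filter drops duplicates and sign-flipped copies", {
  set.seed(3)
  a <- rnorm(80); y <- rbinom(80, 1, 0.5)
  X <- cbind(a = a, dup = a, b = -a, c = rnorm(80))
  out <- correlation_filter(X, y, threshold = 0.9)
  # of {a, dup, b} (all |r| = 1) exactly one survives
  expect_equal(sum(c("a", "dup", "b") %in% out$retained), 1)
  expect_true("c" %in% out$retained)
})

test_that("correlation filter resolves a printed 5-feature toy deterministically", {
  set.seed(4)
  n <- 200
  z <- rnorm(n)
  y <- as.integer(z + rnorm(n) > 0)
  X <- cbind(f1 = z + rnorm(n, 0, 0.1),       # strongly y-related
             f2 = z + rnorm(n, 0, 0.12),      # near-copy of f1
             f3 = rnorm(n),
             f4 = rnorm(n),
             f5 = z + rnorm(n, 0, 0.11))
  out <- correlation_filter(X, y, threshold = 0.9)
  # among the collinear trio, the survivor is the most y-correlated one
  trio <- c("f1", "f2", "f5")
  survivors <- intersect(out$retained, trio)
  expect_equal(length(survivors), 1)
  ry <- abs(cor(X[, trio], y))
  expect_equal(survivors, trio[which.max(ry)])
  expect_true(all(c("f3", "f4") %in% out$retained))
})

test_that("VIF filter keeps orthogonal sets and removes exact collinearity", {
  set.seed(5)
  # columns orthogonal to each other and to the constant => all pairwise
  # correlations are exactly zero
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(100 * 3), ncol = 3))))[, 2:4]
  colnames(Q) <- c("q1", "q2", "q3")
  out <- vif_filter(Q, threshold = 10)
  expect_equal(sort(out$retained), c("q1", "q2", "q3"))
  expect_true(all(abs(out$vif - 1) < 1e-8))

  x1 <- rnorm(60); x2 <- rnorm(60)
  X <- cbind(x1 = x1, x2 = x2, x3 = x1 + x2)
  out2 <- vif_filter(X, threshold = 10)
  expect_equal(length(out2$retained), 2)
  expect_true(all(is.infinite(out2$dropped$vif)))
})

test_that("independent normals have VIF near one", {
  set.seed(6)
  X <- cbind(a = rnorm(1000), b = rnorm(1000))
  out <- vif_filter(X, threshold = 10)
  expect_true(all(abs(out$vif - 1) < 0.05))
})

test_that("the wrapper passes through tiny inputs and keeps planted signal", {
  set.seed(7)
  X <- matrix(rnorm(40), ncol = 1, dimnames = list(NULL, "only"))
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  out <- wrapper_select(X, y, screening_config(seed = 1))
  expect_equal(out$retained, "only")

  n <- 200
  z <- rnorm(n)
  y2 <- rbinom(n, 1, plogis(1.8 * z))
  X2 <- cbind(signal = z, matrix(rnorm(n * 10), ncol = 10))
  colnames(X2) <- c("signal", paste0("n", 1:10))
  cfg <- screening_config(wrapper_max_features = 5, wrapper_forest_size = 300,
                          seed = 2)
  out2 <- wrapper_select(X2, y2, cfg)
  expect_true("signal" %in% out2$retained)
  expect_lte(length(out2$retained), 5)
  # trajectory only ever shrinks
  expect_true(all(diff(out2$trajectory$size) < 0))
})

test_that("the clinical pre-screen applies a strict boundary", {
  uni <- data.frame(variable = c("a", "b", "c"), p = c(0.499, 0.5, 1))
  expect_equal(clinical_prescreen(uni, 0.5), "a")
  expect_message(out <- clinical_prescreen(data.frame(variable = "x", p = 1)),
                 "no clinical variable")
  expect_equal(length(out), 0)
})

test_that("the cascade shrinks monotonically and its report replays", {
  set.seed(8)
  # uniform-shaped features survive the scaled-variance stage (var 1/12)
  n <- 150
  z <- runif(n)
  y <- rbinom(n, 1, plogis(5 * (z - 0.5)))
  X <- cbind(s1 = z + rnorm(n, 0, .04), s2 = z + rnorm(n, 0, .05),
             matrix(runif(n * 12), ncol = 12), const = 1)
  colnames(X) <- c("s1", "s2", paste0("x", 1:12), "const")
  scr <- screen_features(X, y, screening_config(wrapper_forest_size = 200,
                                                seed = 3))
  sizes <- vapply(scr$stages, length, numeric(1))
  expect_true(all(diff(c(ncol(X), sizes)) <= 0))
  # replay: input minus all dropped = retained
  expect_setequal(setdiff(colnames(X), scr$dropped$feature),
                  as.character(scr$retained))
  # stages partition the dropped set
  expect_false(anyDuplicated(scr$dropped$feature) > 0)
})
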