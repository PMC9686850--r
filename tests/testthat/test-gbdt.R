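test_that("the initial score has its closed form", {
  expect_equal(init_f0(c(1, 1, 1, -1)), log(3))
  expect_equal(init_f0(rep(c(0, 1), 10)), 0)
  expect_warning(f <- init_f0(rep(1, 5)), "clamped")
  expect_equal(f, 10)
})

test_that("negative gradients follow the closed form and stay inside (-1, 1)", {
  expect_equal(negative_gradient(1, 0), 0.5)
  expect_equal(negative_gradient(-1, 0), -0.5)
  expect_lt(negative_gradient(1, 50), 1e-12)
  set.seed(1)
  y <- sample(c(-1, 1), 100, replace = TRUE)
  f <- rnorm(100, 0, 3)
  r <- negative_gradient(y, f)
  expect_true(all(abs(r) < 1))
  expect_equal(r, y / (1 + exp(y * f)))
})

test_that("tree splits match an exhaustive search oracle", {
  # 8-point 1-D data set
  x <- matrix(c(0.1, 0.4, 0.9, 1.3, 2.0, 2.6, 3.1, 3.8), ncol = 1)
  r <- c(0.4, 0.5, 0.45, 0.42, -0.38, -0.45, -0.5, -0.4)
  tree <- fit_regression_tree(x, r, depth = 1, min_leaf = 1)
  split <- tree$nodes[[1]]
  # oracle: try every midpoint
  xs <- sort(unique(x))
  best <- -Inf; best_t <- NA
  for (t in (xs[-length(xs)] + xs[-1]) / 2) {
    L <- x[, 1] < t
    red <- sum(r)^2 / length(r) * -1 +
      sum(r[L])^2 / sum(L) + sum(r[!L])^2 / sum(!L)
    if (red > best) { best <- red; best_t <- t }
  }
  expect_equal(split$threshold, best_t)

  # residuals perfectly split by x < 0
  x2 <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  r2 <- c(0.5, 0.5, 0.5, -0.5, -0.5, -0.5)
  t2 <- fit_regression_tree(x2, r2, depth = 3, min_leaf = 1)
  expect_equal(t2$nodes[[1]]$threshold, 0)
  expect_true(is.na(t2$nodes[[t2$nodes[[1]]$left]]$feature))

  # min_leaf = n forces a single leaf
  t3 <- fit_regression_tree(x2, r2, depth = 3, min_leaf = 6)
  expect_true(is.na(t3$nodes[[1]]$feature))
})

test_that("leaf values implement the closed-form ratio with guards", {
  x <- matrix(c(-1, -1, 1, 1), ncol = 1)
  r <- c(0.5, 0.5, -0.2, -0.2)
  tree <- fit_regression_tree(x, r, depth = 1, min_leaf = 1)
  g <- leaf_values(tree, r)
  # left leaf r = {0.5, 0.5}: c = 1 / (2 * 0.25) = 2
  left_id <- as.character(tree$nodes[[1]]$left)
  expect_equal(unname(g[left_id]), 2.0)

  r2 <- c(0.5, -0.5, 0.1, -0.1)
  tree2 <- fit_regression_tree(x, r2 * 0, depth = 1, min_leaf = 1)
  g2 <- leaf_values(tree2, c(0.5, -0.5, 0.5, -0.5))
  expect_equal(unname(g2["1"]), 0)  # cancellation

  g3 <- leaf_values(tree2, rep(1e-13, 4))
  expect_equal(unname(g3["1"]), 0)  # vanishing denominator guard
})

test_that("boosting matches an independent straight-line oracle to 1e-12", {
  set.seed(5)
  X <- cbind(a = c(0.3, 1.2, -0.5, 2.2, -1.7, 0.9, -0.2, 1.5, -2.0, 0.4, 1.1, -0.8),
             b = rnorm(12), c = rnorm(12))
  y <- c(1, 1, 0, 1, 0, 1, 0, 1, 0, 0, 1, 0)
  for (M in c(1, 3)) {
    cfg <- gbdt_config(n_trees = M, shrinkage = 0.05, tree_depth = 1,
                       min_leaf = 1)
    fit <- gbdt(X, y, cfg)
    orc <- oracle_gbdt_stump(X, y, M, 0.05)
    expect_equal(fit$f0, orc$f0, tolerance = 1e-14)
    expect_equal(predict(fit, X, type = "link"), orc$f, tolerance = 1e-12)
  }
})

test_that("zero shrinkage keeps predictions at the initial score", {
  set.seed(6)
  X <- matrix(rnorm(40), ncol = 2)
  y <- rbinom(20, 1, 0.5); y[1:2] <- c(0, 1)
  fit <- gbdt(X, y, gbdt_config(n_trees = 5, shrinkage = 0))
  expect_true(all(abs(predict(fit, X, type = "link") - fit$f0) < 1e-12))
})

test_that("linearly separable data reach training AUC 1", {
  set.seed(7)
  n <- 60
  X <- cbind(x1 = c(runif(n / 2, -3, -1), runif(n / 2, 1, 3)), x2 = rnorm(n))
  y <- rep(c(0, 1), each = n / 2)
  fit <- gbdt(X, y, gbdt_config(n_trees = 50, tree_depth = 1, min_leaf = 1))
  expect_equal(auc(predict(fit, X), y), 1.0)
})

test_that("probabilities follow the logistic link monotonically", {
  set.seed(8)
  X <- matrix(rnorm(60), ncol = 2)
  y <- as.integer(X[, 1] > 0)
  fit <- gbdt(X, y, gbdt_config(n_trees = 20))
  f <- predict(fit, X, type = "link")
  p <- predict(fit, X, type = "response")
  expect_equal(p, 1 / (1 + exp(-f)))
  o <- order(f)
  expect_true(all(diff(p[o]) >= 0))
  # closed forms
  expect_equal(1 / (1 + exp(-log(3))), 0.75)
})

test_that("training deviance never increases without bagging", {
  set.seed(9)
  X <- matrix(rnorm(200 * 4), ncol = 4)
  y <- rbinom(200, 1, plogis(X[, 1] - X[, 2]))
  fit <- gbdt(X, y, gbdt_config(n_trees = 80))
  expect_true(all(diff(fit$train_deviance) <= 1e-12))
})

test_that("serialization round-trips bit-identically", {
  set.seed(10)
  X <- matrix(rnorm(50 * 3), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(50, 1, plogis(X[, 1]))
  fit <- gbdt(X, y, gbdt_config(n_trees = 15))
  path <- tempfile(fileext = ".json")
  gbdt_save(fit, path)
  fit2 <- gbdt_load(path)
  expect_identical(predict(fit, X), predict(fit2, X))
})

test_that("relative influence sums to 100 and tracks usage", {
  set.seed(11)
  X <- cbind(only = rnorm(100), unused = rep(0, 100))
  y <- as.integer(X[, 1] > 0)
  fit <- gbdt(X, y, gbdt_config(n_trees = 20, tree_depth = 1, min_leaf = 5))
  imp <- gbdt_importance(fit)
  expect_equal(sum(imp), 100)
  expect_equal(unname(imp["only"]), 100)
  expect_equal(unname(imp["unused"]), 0)
})

test_that("duplicated informative features share the original's influence", {
  set.seed(12)
  n <- 300
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(2 * z))
  noise <- matrix(rnorm(n * 2), ncol = 2, dimnames = list(NULL, c("u", "v")))
  f_single <- gbdt(cbind(s = z, noise), y, gbdt_config(n_trees = 60))
  f_dup <- gbdt(cbind(s = z, s2 = z, noise), y, gbdt_config(n_trees = 60))
  i1 <- gbdt_importance(f_single)["s"]
  i2 <- sum(gbdt_importance(f_dup)[c("s", "s2")])
  expect_lt(abs(i2 - i1) / i1, 0.2)
})

test_that("partial dependence is flat for unused features, monotone for planted", {
  set.seed(13)
  n <- 250
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, plogis(2.5 * X[, 1]))
  fit <- gbdt(X, y, gbdt_config(n_trees = 80))
  pd1 <- partial_dependence(fit, X, "x1")
  expect_gt(cor(pd1$value, pd1$score, method = "spearman"), 0.95)

  fit0 <- gbdt(X, y, gbdt_config(n_trees = 5, shrinkage = 0))
  pd0 <- partial_dependence(fit0, X, "x2")
  expect_lt(diff(range(pd0$score)), 1e-12)
})

test_that("CV-optimal iteration count behaves at both extremes", {
  set.seed(14)
  n <- 120
  X <- cbind(x = rnorm(n), z = rnorm(n))
  y <- rbinom(n, 1, plogis(3 * X[, 1]))
  cfg <- gbdt_config(n_trees = 60, seed = 4)
  opt <- optimal_iterations(X, y, cfg)
  expect_lte(opt$cv_deviance[opt$best_iter], opt$cv_deviance[1])
  opt2 <- optimal_iterations(X, y, cfg)
  expect_identical(opt$best_iter, opt2$best_iter)  # deterministic

  # pure noise: the optimum comes early in most replicates
  early <- 0
  for (s in 1:6) {
    set.seed(s)
    Xn <- matrix(rnorm(80 * 3), ncol = 3)
    yn <- rbinom(80, 1, 0.5)
    cfgn <- gbdt_config(n_trees = 100, seed = s)
    on <- optimal_iterations(Xn, yn, cfgn)
    if (on$best_iter <= 10) early <- early + 1
  }
  expect_gte(early, 4)
})
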