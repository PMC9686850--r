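#' GBDT configuration
#'
#' @param n_trees number of boosting iterations M. The desk-scale default is
#'   500; `full_scale = TRUE` in [pipeline_config()] switches to 10000.
#' @param shrinkage learning rate applied to every tree's contribution.
#' @param tree_depth maximum split depth of each regression tree.
#' @param min_leaf minimum rows per leaf.
#' @param bag_fraction fraction of rows sampled (without replacement) per
#'   iteration; 1 disables bagging.
#' @param cv_folds_internal folds for [optimal_iterations()].
#' @param seed integer seed (used for bagging and internal CV).
#' @return An object of class `rd_gbdt_config`.
#' @export
gbdt_config <- function(n_trees = 500, shrinkage = 0.05, tree_depth = 3,
                        min_leaf = 5, bag_fraction = 1.0,
                        cv_folds_internal = 5, seed = 1) {
  stopifnot(n_trees >= 1, shrinkage >= 0, shrinkage <= 1, tree_depth >= 1,
            min_leaf >= 1, bag_fraction > 0, bag_fraction <= 1)
  structure(list(n_trees = as.integer(n_trees), shrinkage = shrinkage,
                 tree_depth = as.integer(tree_depth),
                 min_leaf = as.integer(min_leaf),
                 bag_fraction = bag_fraction,
                 cv_folds_internal = as.integer(cv_folds_internal),
                 seed = as.integer(seed)),
            class = "rd_gbdt_config")
}

#' Initial boosting score
#'
#' Minimizer of the total Bernoulli loss `log(1 + exp(-y f))` over a
#' constant score: `f0 = log(n+ / n-)` with labels coded -1/+1. If one class
#' is absent the value is clamped to +/-10 with a warning.
#'
#' @param y labels in -1/+1 (0/1 input is recoded).
#' @return Scalar f0.
#' @export
init_f0 <- function(y) {
  y <- recode_pm1(y)
  npos <- sum(y > 0); nneg <- sum(y < 0)
  if (npos == 0 || nneg == 0) {
    warning("single-class labels: f0 clamped to +/-10")
    return(if (npos == 0) -10 else 10)
  }
  log(npos / nneg)
}

recode_pm1 <- function(y) {
  u <- sort(unique(y))
  if (all(u %in% c(-1, 1))) return(as.numeric(y))
  if (all(u %in% c(0, 1))) return(ifelse(y > 0, 1, -1))
  if (is.factor(y) || is.character(y)) {
    f <- as.factor(y)
    if (nlevels(f) != 2) stop("y must be binary")
    return(ifelse(as.integer(f) == 2, 1, -1))
  }
  stop("y must be binary")
}

#' Negative gradient of the Bernoulli loss
#'
#' `r_i = y_i / (1 + exp(y_i f_i))` with labels in -1/+1; always strictly
#' inside (-1, 1).
#'
#' @param y labels (-1/+1 or 0/1).
#' @param f current scores.
#' @return Numeric residual vector.
#' @export
negative_gradient <- function(y, f) {
  y <- recode_pm1(y)
  y / (1 + exp(y * f))
}

# Greedy least-squares regression tree on residuals. Nodes are stored in a
# data.frame; leaves have feature = NA. Deterministic: ties in the split
# search go to the lower feature index, then the lower threshold.
fit_regression_tree_impl <- function(X, r, depth, min_leaf) {
  nodes <- list()
  new_node <- function() length(nodes) + 1L
  build <- function(idx, d) {
    id <- new_node()
    nodes[[id]] <<- list(feature = NA_integer_, threshold = NA_real_,
                         left = NA_integer_, right = NA_integer_,
                         rows = idx, improvement = 0)
    n <- length(idx)
    if (d >= depth || n < 2 * min_leaf) return(id)
    rv <- r[idx]
    if (max(rv) - min(rv) == 0) return(id)
    best <- list(red = 0, j = NA, thr = NA)
    tot <- sum(rv)
    for (j in seq_len(ncol(X))) {
      x <- X[idx, j]
      o <- order(x, method = "radix")
      xs <- x[o]; rs <- rv[o]
      cs <- cumsum(rs)
      nl <- seq_len(n - 1)
      valid <- xs[-n] < xs[-1] & nl >= min_leaf & (n - nl) >= min_leaf
      if (!any(valid)) next
      red <- cs[-n]^2 / nl + (tot - cs[-n])^2 / (n - nl) - tot^2 / n
      red[!valid] <- -Inf
      b <- which.max(red)
      if (red[b] > best$red + 1e-12) {
        best <- list(red = red[b], j = j, thr = (xs[b] + xs[b + 1]) / 2)
      }
    }
    if (is.na(best$j)) return(id)
    go <- X[idx, best$j] < best$thr
    l <- build(idx[go], d + 1)
    rt <- build(idx[!go], d + 1)
    nodes[[id]]$feature <<- best$j
    nodes[[id]]$threshold <<- best$thr
    nodes[[id]]$left <<- l
    nodes[[id]]$right <<- rt
    nodes[[id]]$improvement <<- best$red
    id
  }
  build(seq_len(nrow(X)), 0)
  nodes
}

#' Fit a regression tree to residuals
#'
#' Greedy binary splitting minimizing the squared error of the residuals,
#' respecting a depth limit and a minimum leaf size. Constant residuals give
#' a single-leaf tree. Deterministic given the input order.
#'
#' @param X numeric predictor matrix.
#' @param r numeric residual targets.
#' @param depth maximum depth (1 = a single split).
#' @param min_leaf minimum rows per leaf.
#' @return An object of class `rd_tree` (list of nodes; leaves carry the row
#'   sets used to fit them).
#' @export
fit_regression_tree <- function(X, r, depth = 3, min_leaf = 5) {
  X <- as.matrix(X)
  structure(list(nodes = fit_regression_tree_impl(X, r, depth, min_leaf)),
            class = "rd_tree")
}

# leaf index (into nodes) for every row of X
tree_leaf_of <- function(nodes, X) {
  n <- nrow(X)
  leaf <- rep(1L, n)
  active <- rep(TRUE, n)
  repeat {
    done <- TRUE
    for (id in unique(leaf[active])) {
      nd <- nodes[[id]]
      if (is.na(nd$feature)) next
      done <- FALSE
      rows <- which(leaf == id)
      go <- X[rows, nd$feature] < nd$threshold
      leaf[rows[go]] <- nd$left
      leaf[rows[!go]] <- nd$right
    }
    if (done) break
  }
  leaf
}

#' Leaf values from the closed-form approximation
#'
#' Per-leaf value `c = sum(r) / sum(|r| (1 - |r|))` over the rows in the
#' leaf. A vanishing denominator gives 0; values are capped at +/-1000 with
#' a warning.
#'
#' @param tree an `rd_tree`.
#' @param r residual vector used to fit the tree.
#' @return Named numeric vector of leaf values indexed by node id.
#' @export
leaf_values <- function(tree, r) {
  nodes <- tree$nodes
  leaves <- which(vapply(nodes, function(nd) is.na(nd$feature), logical(1)))
  g <- vapply(leaves, function(id) {
    rv <- r[nodes[[id]]$rows]
    den <- sum(abs(rv) * (1 - abs(rv)))
    if (den < 1e-12) return(0)
    num <- sum(rv)
    val <- num / den
    if (abs(val) > 1e3) {
      warning("leaf value capped at +/-1000")
      val <- sign(val) * 1e3
    }
    val
  }, numeric(1))
  setNames(g, leaves)
}

#' Gradient-boosted decision trees with Bernoulli loss
#'
#' Stagewise additive model for binary outcomes: starting from
#' `f0 = log(n+/n-)`, each iteration fits a regression tree to the negative
#' gradient `r_i = y_i / (1 + exp(y_i f_i))`, sets leaf values by the
#' closed-form `sum(r) / sum(|r|(1-|r|))` and updates
#' `f <- f + shrinkage * gamma`. Predicted probabilities use the logistic
#' link `p = 1 / (1 + exp(-f))`.
#'
#' @param x numeric predictor matrix or data.frame.
#' @param y binary outcome (0/1, -1/+1, logical or 2-level factor).
#' @param cfg an [gbdt_config()].
#' @param valid optional list(x, y) tracked per iteration (held-out
#'   deviance), used by [optimal_iterations()].
#' @return An object of class `gbdt` with components `f0`, `trees`,
#'   `shrinkage`, `train_deviance`, `valid_deviance` (if tracked),
#'   `feature_names` and `config`.
#' @seealso [predict.gbdt()], [gbdt_importance()], [partial_dependence()],
#'   [optimal_iterations()]
#' @export
gbdt <- function(x, y, cfg = gbdt_config(), valid = NULL) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("NA in features")
  yv <- recode_pm1(y)
  if (length(unique(yv)) < 2) stop("y must contain both classes")
  n <- nrow(X)
  f0 <- init_f0(yv)
  f <- rep(f0, n)
  fv <- NULL
  if (!is.null(valid)) {
    Xv <- as.matrix(valid$x)
    yvv <- recode_pm1(valid$y)
    fv <- rep(f0, nrow(Xv))
  }
  nu <- cfg$shrinkage
  dev <- function(yy, ff) {
    z <- -yy * ff
    mean(ifelse(z > 30, z, log1p(exp(pmin(z, 30)))))
  }
  trees <- vector("list", cfg$n_trees)
  tr_dev <- numeric(cfg$n_trees)
  va_dev <- if (!is.null(valid)) numeric(cfg$n_trees) else NULL
  bag <- cfg$bag_fraction < 1
  rng_seed <- derive_seed(cfg$seed, "bag")
  with_seed(rng_seed, {
    for (m in seq_len(cfg$n_trees)) {
      r <- yv / (1 + exp(yv * f))
      rows <- if (bag) sort(sample.int(n, max(2 * cfg$min_leaf,
                                              round(cfg$bag_fraction * n))))
              else seq_len(n)
      nodes <- fit_regression_tree_impl(X[rows, , drop = FALSE], r[rows],
                                        cfg$tree_depth, cfg$min_leaf)
      tree <- structure(list(nodes = nodes), class = "rd_tree")
      gam <- leaf_values(tree, r[rows])
      # strip row sets (kept only during fitting) and attach leaf values
      slim <- lapply(seq_along(nodes), function(id) {
        nd <- nodes[[id]]
        list(feature = nd$feature, threshold = nd$threshold,
             left = nd$left, right = nd$right,
             improvement = nd$improvement,
             value = if (is.na(nd$feature)) unname(gam[as.character(id)]) else NA_real_)
      })
      leaf_all <- tree_leaf_of(slim, X)
      f <- f + nu * vapply(slim[leaf_all], `[[`, numeric(1), "value")
      tr_dev[m] <- dev(yv, f)
      if (!is.null(valid)) {
        leaf_v <- tree_leaf_of(slim, Xv)
        fv <- fv + nu * vapply(slim[leaf_v], `[[`, numeric(1), "value")
        va_dev[m] <- dev(yvv, fv)
      }
      trees[[m]] <- slim
    }
  })
  structure(list(f0 = f0, trees = trees, shrinkage = nu,
                 train_deviance = tr_dev, valid_deviance = va_dev,
                 feature_names = colnames(X),
                 n = n, config = cfg),
            class = "gbdt")
}

#' @export
print.gbdt <- function(x, ...) {
  cat(sprintf("<gbdt> %d trees, depth %d, shrinkage %g, f0 = %.4f, n = %d\n",
              length(x$trees), x$config$tree_depth, x$shrinkage, x$f0, x$n))
  cat(sprintf("final training deviance: %.5f\n",
              x$train_deviance[length(x$train_deviance)]))
  invisible(x)
}

#' @export
summary.gbdt <- function(object, ...) {
  imp <- gbdt_importance(object)
  cat(sprintf("Gradient-boosted trees: %d iterations, shrinkage %g\n",
              length(object$trees), object$shrinkage))
  cat("Relative influence (top 10):\n")
  top <- head(sort(imp, decreasing = TRUE), 10)
  for (nm in names(top)) cat(sprintf("  %-40s %6.2f\n", nm, top[nm]))
  invisible(imp)
}

#' Predict from a fitted GBDT
#'
#' @param object a `gbdt` model.
#' @param newdata numeric matrix/data.frame with the training columns.
#' @param type `"response"` for probabilities `1/(1+exp(-f))`, `"link"` for
#'   the raw score f.
#' @param n_trees use only the first `n_trees` trees (e.g. a CV-chosen
#'   iteration count).
#' @param ... unused.
#' @return Numeric vector.
#' @export
predict.gbdt <- function(object, newdata, type = c("response", "link"),
                         n_trees = NULL, ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(X)))
    X <- X[, object$feature_names, drop = FALSE]
  f <- rep(object$f0, nrow(X))
  use <- seq_len(if (is.null(n_trees)) length(object$trees)
                 else min(n_trees, length(object$trees)))
  for (m in use) {
    slim <- object$trees[[m]]
    leaf <- tree_leaf_of(slim, X)
    f <- f + object$shrinkage * vapply(slim[leaf], `[[`, numeric(1), "value")
  }
  if (type == "link") f else 1 / (1 + exp(-f))
}

#' @export
fitted.gbdt <- function(object, ...) {
  stop("gbdt does not store training rows; call predict() with the data")
}

#' Residuals of a GBDT fit
#'
#' Negative-gradient residuals at the model's final scores.
#'
#' @param object a `gbdt` model.
#' @param x,y the training data.
#' @param ... unused.
#' @return Numeric vector `y/(1+exp(y f))`.
#' @export
residuals.gbdt <- function(object, x, y, ...) {
  f <- predict(object, x, type = "link")
  negative_gradient(y, f)
}

#' Training-deviance trace plot
#'
#' @param x a `gbdt` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gbdt <- function(x, ...) {
  graphics::plot(seq_along(x$train_deviance), x$train_deviance, type = "l",
                 xlab = "iteration", ylab = "Bernoulli deviance",
                 main = "GBDT training deviance", ...)
  if (!is.null(x$valid_deviance))
    graphics::lines(seq_along(x$valid_deviance), x$valid_deviance, lty = 2)
  invisible(x)
}

#' Relative influence of each feature
#'
#' Squared-error improvement of every split, accumulated per feature over
#' all trees and normalized to sum to 100.
#'
#' @param model a `gbdt` model.
#' @return Named numeric vector (percent).
#' @export
gbdt_importance <- function(model) {
  p <- length(model$feature_names)
  imp <- setNames(rep(0, p), model$feature_names)
  for (tree in model$trees) {
    for (nd in tree) {
      if (!is.na(nd$feature))
        imp[nd$feature] <- imp[nd$feature] + nd$improvement
    }
  }
  if (sum(imp) > 0) imp <- imp / sum(imp) * 100
  imp
}

#' Partial dependence of the risk score on one feature
#'
#' `PD(v) = mean_i f(x_i with feature := v)` on the link (risk-score) scale.
#'
#' @param model a `gbdt` model.
#' @param X data the average is taken over.
#' @param feature feature name.
#' @param grid evaluation values (default: 20 quantiles of the feature).
#' @return data.frame with `value` and `score`.
#' @export
partial_dependence <- function(model, X, feature, grid = NULL) {
  X <- as.matrix(X)
  if (is.null(grid))
    grid <- unique(quantile(X[, feature], seq(0.025, 0.975, length.out = 20),
                            names = FALSE))
  score <- vapply(grid, function(v) {
    Xm <- X
    Xm[, feature] <- v
    mean(predict(model, Xm, type = "link"))
  }, numeric(1))
  data.frame(value = grid, score = score)
}

#' CV-optimal number of boosting iterations
#'
#' Stratified internal cross-validation: each fold's model tracks held-out
#' Bernoulli deviance per iteration; the optimum is the iteration minimizing
#' the mean held-out deviance.
#'
#' @param x,y training data.
#' @param cfg an [gbdt_config()].
#' @return List with `best_iter` and `cv_deviance` (per-iteration mean).
#' @export
optimal_iterations <- function(x, y, cfg = gbdt_config()) {
  X <- as.matrix(x)
  yv <- as.integer(as.factor(y)) - 1L
  folds <- stratified_folds(yv, cfg$cv_folds_internal,
                            derive_seed(cfg$seed, "gbdtcv"))
  devs <- matrix(NA_real_, cfg$n_trees, max(folds))
  for (k in seq_len(max(folds))) {
    tr <- folds != k
    fit <- gbdt(X[tr, , drop = FALSE], yv[tr], cfg,
                valid = list(x = X[!tr, , drop = FALSE], y = yv[!tr]))
    devs[, k] <- fit$valid_deviance
  }
  mean_dev <- rowMeans(devs)
  list(best_iter = which.min(mean_dev), cv_deviance = mean_dev)
}

#' Serialize a GBDT model to JSON
#'
#' @param model a `gbdt` model.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
gbdt_save <- function(model, path) {
  obj <- list(f0 = model$f0, shrinkage = model$shrinkage,
              feature_names = model$feature_names, n = model$n,
              train_deviance = model$train_deviance,
              config = unclass(model$config),
              trees = model$trees)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Load a GBDT model serialized with [gbdt_save()]
#'
#' @param path JSON file.
#' @return A `gbdt` model.
#' @export
gbdt_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  trees <- lapply(obj$trees, function(tree)
    lapply(tree, function(nd)
      list(feature = if (is.null(nd$feature)) NA_integer_ else as.integer(nd$feature),
           threshold = if (is.null(nd$threshold)) NA_real_ else as.numeric(nd$threshold),
           left = if (is.null(nd$left)) NA_integer_ else as.integer(nd$left),
           right = if (is.null(nd$right)) NA_integer_ else as.integer(nd$right),
           improvement = as.numeric(nd$improvement),
           value = if (is.null(nd$value)) NA_real_ else as.numeric(nd$value))))
  cfg <- do.call(gbdt_config, obj$config[setdiff(names(obj$config), NULL)])
  structure(list(f0 = as.numeric(obj$f0), trees = trees,
                 shrinkage = as.numeric(obj$shrinkage),
                 train_deviance = as.numeric(unlist(obj$train_deviance)),
                 valid_deviance = NULL,
                 feature_names = as.character(unlist(obj$feature_names)),
                 n = as.integer(obj$n), config = cfg),
            class = "gbdt")
}
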