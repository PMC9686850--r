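#' Screening cascade configuration
#'
#' @param mwu_alpha significance level of the Mann-Whitney U filter.
#' @param variance_threshold variance cut on min-max scaled features
#'   (features with variance <= threshold are dropped).
#' @param corr_threshold absolute Pearson correlation above which one member
#'   of a feature pair is dropped.
#' @param vif_threshold variance inflation factor limit.
#' @param wrapper_max_features maximum size of the wrapper-selected subset.
#' @param wrapper_forest_size trees per random forest in the wrapper.
#' @param cv_folds stratified folds for the wrapper's CV AUC.
#' @param seed integer seed.
#' @return An object of class `rd_screening_config`.
#' @export
screening_config <- function(mwu_alpha = 0.05, variance_threshold = 0.05,
                             corr_threshold = 0.9, vif_threshold = 10,
                             wrapper_max_features = 20,
                             wrapper_forest_size = 500,
                             cv_folds = 5, seed = 1) {
  stopifnot(mwu_alpha > 0, variance_threshold >= 0, corr_threshold > 0,
            vif_threshold > 0, wrapper_max_features >= 1)
  structure(list(mwu_alpha = mwu_alpha,
                 variance_threshold = variance_threshold,
                 corr_threshold = corr_threshold,
                 vif_threshold = vif_threshold,
                 wrapper_max_features = as.integer(wrapper_max_features),
                 wrapper_forest_size = as.integer(wrapper_forest_size),
                 cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "rd_screening_config")
}

# Two-sided Mann-Whitney U p-value: normal approximation with tie and
# continuity corrections (the wilcox.test default). Constant features give
# p = 1.
mwu_test <- function(x, y1) {
  n1 <- sum(y1); n2 <- sum(!y1)
  r <- rank(x)
  U <- sum(r[y1]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(x)
  s2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (s2 <= 0) return(c(U = U, p = 1))
  z <- max(0, abs(U - n1 * n2 / 2) - 0.5) / sqrt(s2)
  c(U = U, p = min(1, 2 * pnorm(-z)))
}

#' Mann-Whitney U filter
#'
#' Keeps features whose two-sided MWU p-value (normal approximation with tie
#' correction) is below `alpha`. The normalized statistic `U / (n1 n2)`
#' equals the feature's AUC as a classifier score.
#'
#' @param X numeric feature matrix (named columns).
#' @param y binary labels.
#' @param alpha significance level.
#' @return List with `retained` (names), `p` (named p-values) and `auc`
#'   (named `U/(n1 n2)` values).
#' @export
mwu_filter <- function(X, y, alpha = 0.05) {
  X <- as.matrix(X)
  y1 <- as.logical(as.integer(as.factor(y)) - 1L)
  res <- apply(X, 2, mwu_test, y1 = y1)
  p <- setNames(as.numeric(res["p", ]), colnames(X))
  u <- setNames(as.numeric(res["U", ]) / (sum(y1) * sum(!y1)), colnames(X))
  list(retained = colnames(X)[p < alpha], p = p, auc = u)
}

#' Variance filter
#'
#' Computes the population variance of each min-max scaled feature and drops
#' those with variance <= `threshold`. Constant features scale to variance 0
#' and are always dropped for any non-negative threshold.
#'
#' @param X numeric feature matrix.
#' @param threshold variance threshold on the scaled copy.
#' @return List with `retained` and named `variance`.
#' @export
variance_filter <- function(X, threshold = 0.05) {
  X <- as.matrix(X)
  v <- apply(X, 2, function(x) {
    r <- range(x)
    if (r[1] == r[2]) return(0)
    s <- (x - r[1]) / (r[2] - r[1])
    mean((s - mean(s))^2)
  })
  list(retained = colnames(X)[v > threshold], variance = v)
}

#' Pairwise correlation filter
#'
#' Processes feature pairs with `|Pearson r| >= threshold` in order of
#' decreasing `|r|` (ties broken lexicographically by the pair's names); of
#' each pair the member with the smaller absolute point-biserial correlation
#' to the outcome is dropped. Pairs with an already-dropped member are
#' skipped.
#'
#' @param X numeric feature matrix.
#' @param y binary labels.
#' @param threshold absolute correlation cut.
#' @return List with `retained` and `dropped` (data.frame of feature,
#'   partner, r).
#' @export
correlation_filter <- function(X, y, threshold = 0.9) {
  X <- as.matrix(X)
  yv <- as.numeric(as.factor(y)) - 1
  p <- ncol(X)
  if (p < 2) return(list(retained = col_names(X),
                         dropped = data.frame(feature = character(),
                                              partner = character(),
                                              r = numeric())))
  R <- suppressWarnings(cor(X))
  R[is.na(R)] <- 0
  ry <- abs(suppressWarnings(cor(X, yv)))
  ry[is.na(ry)] <- 0
  hit <- which(abs(R) >= threshold & upper.tri(R), arr.ind = TRUE)
  if (nrow(hit)) {
    nm <- colnames(X)
    ord <- order(-abs(R[hit]), nm[hit[, 1]], nm[hit[, 2]])
    hit <- hit[ord, , drop = FALSE]
  }
  alive <- rep(TRUE, p)
  drop_log <- list()
  for (t in seq_len(nrow(hit))) {
    i <- hit[t, 1]; j <- hit[t, 2]
    if (!alive[i] || !alive[j]) next
    # keep the member more correlated with the outcome
    if (ry[i] > ry[j]) victim <- j
    else if (ry[j] > ry[i]) victim <- i
    else victim <- if (colnames(X)[i] <= colnames(X)[j]) j else i
    alive[victim] <- FALSE
    drop_log[[length(drop_log) + 1]] <-
      data.frame(feature = colnames(X)[victim],
                 partner = colnames(X)[setdiff(c(i, j), victim)],
                 r = R[i, j])
  }
  list(retained = colnames(X)[alive],
       dropped = if (length(drop_log)) do.call(rbind, drop_log)
                 else data.frame(feature = character(),
                                 partner = character(), r = numeric()))
}

compute_vifs <- function(X) {
  # VIF_j = 1/(1 - R^2_j); exact collinearity yields Inf
  p <- ncol(X)
  sds <- apply(X, 2, sd)
  v <- rep(Inf, p)
  names(v) <- colnames(X)
  if (any(sds == 0)) return(v)
  R <- cor(X)
  inv <- tryCatch(chol2inv(chol(R)), error = function(e) NULL)
  if (!is.null(inv)) return(setNames(diag(inv), colnames(X)))
  # singular: R^2 via rank checks per column
  qx <- qr(scale(X))
  aliased <- rep(FALSE, p)
  if (qx$rank < p) aliased[qx$pivot[(qx$rank + 1):p]] <- TRUE
  for (j in seq_len(p)) {
    if (aliased[j]) { v[j] <- Inf; next }
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    v[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  v
}

#' Iterative VIF filter
#'
#' Repeatedly removes the feature with the largest variance inflation factor
#' while any VIF >= `threshold`. Exactly collinear (aliased) columns have
#' infinite VIF and are removed first, one recorded per column; ties are
#' broken by name order for determinism.
#'
#' @param X numeric feature matrix.
#' @param threshold VIF limit (classically 10).
#' @return List with `retained`, `dropped` (data.frame feature/vif) and
#'   `vif` (final VIFs of the retained set).
#' @export
vif_filter <- function(X, threshold = 10) {
  X <- as.matrix(X)
  dropped <- list()
  # shed exactly-aliased columns first (beyond the design rank)
  if (ncol(X) >= 2) {
    qx <- qr(scale(X))
    if (qx$rank < ncol(X)) {
      bad <- sort(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]])
      for (b in bad)
        dropped[[length(dropped) + 1]] <- data.frame(feature = b, vif = Inf)
      X <- X[, setdiff(colnames(X), bad), drop = FALSE]
    }
  }
  while (ncol(X) >= 2) {
    v <- compute_vifs(X)
    if (max(v) < threshold) break
    worst <- names(v)[v == max(v)]
    worst <- sort(worst)[1]
    dropped[[length(dropped) + 1]] <- data.frame(feature = worst,
                                                 vif = max(v))
    X <- X[, setdiff(colnames(X), worst), drop = FALSE]
  }
  final <- if (ncol(X) >= 2) compute_vifs(X)
           else setNames(rep(1, ncol(X)), col_names(X))
  list(retained = col_names(X),
       dropped = if (length(dropped)) do.call(rbind, dropped)
                 else data.frame(feature = character(), vif = numeric()),
       vif = final)
}

col_names <- function(X) {
  if (is.null(colnames(X))) character(0) else colnames(X)
}

stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    f <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
}

ranger_cv_auc <- function(X, y, folds, n_trees, seed) {
  aucs <- numeric(max(folds))
  yf <- factor(y)
  for (k in seq_len(max(folds))) {
    tr <- folds != k
    fit <- ranger::ranger(x = X[tr, , drop = FALSE], y = yf[tr],
                          num.trees = n_trees, probability = TRUE,
                          num.threads = 1, seed = seed + k)
    pr <- predict(fit, data = X[!tr, , drop = FALSE],
                  num.threads = 1)$predictions[, 2]
    aucs[k] <- auc(pr, y[!tr])
  }
  mean(aucs)
}

#' Wrapper (encapsulation) feature selection
#'
#' Sequential backward elimination guided by random-forest permutation
#' importance: at each step the current subset's stratified CV AUC is
#' recorded, then the least important ~10% of features (one at a time once
#' the set is within twice `wrapper_max_features`) are removed. The returned
#' subset is the one with the highest mean CV AUC among sizes
#' `<= wrapper_max_features`; ties favour the smaller subset. Deterministic
#' under the config seed.
#'
#' @param X numeric feature matrix.
#' @param y binary labels.
#' @param cfg an [screening_config()].
#' @return List with `retained`, and `trajectory` (data.frame of subset size
#'   and mean CV AUC, largest first).
#' @export
wrapper_select <- function(X, y, cfg = screening_config()) {
  X <- as.matrix(X)
  y <- as.integer(as.factor(y)) - 1L
  if (ncol(X) < 2)
    return(list(retained = col_names(X),
                trajectory = data.frame(size = ncol(X), cv_auc = NA_real_)))
  folds <- stratified_folds(y, cfg$cv_folds, derive_seed(cfg$seed, "wrapfolds"))
  current <- colnames(X)
  traj <- list()
  subsets <- list()
  step <- 0
  while (TRUE) {
    step <- step + 1
    Xc <- X[, current, drop = FALSE]
    cv <- ranger_cv_auc(Xc, y, folds, cfg$wrapper_forest_size,
                        derive_seed(cfg$seed, paste0("wrapcv", step)))
    traj[[step]] <- data.frame(size = length(current), cv_auc = cv)
    subsets[[step]] <- current
    if (length(current) <= 1) break
    fit <- ranger::ranger(x = Xc, y = factor(y),
                          num.trees = cfg$wrapper_forest_size,
                          importance = "permutation", probability = TRUE,
                          num.threads = 1,
                          seed = derive_seed(cfg$seed, paste0("wrapimp", step)))
    imp <- ranger::importance(fit)
    n_drop <- if (length(current) > 2 * cfg$wrapper_max_features)
      max(1L, floor(0.1 * length(current))) else 1L
    # drop the least important features; ties by name for determinism
    ord <- order(imp, names(imp))
    current <- setdiff(current, names(imp)[ord[seq_len(n_drop)]])
  }
  traj <- do.call(rbind, traj)
  ok <- which(traj$size <= cfg$wrapper_max_features)
  if (!length(ok)) ok <- which.min(traj$size)
  best <- ok[order(-traj$cv_auc[ok], traj$size[ok])][1]
  list(retained = subsets[[best]], trajectory = traj)
}

#' Clinical pre-screen
#'
#' Keeps clinical variables whose univariate p-value is strictly below
#' `alpha` (default 0.5 — a deliberately permissive gate feeding the
#' multivariable logistic regression).
#'
#' @param univariate data.frame from [univariate_table()] with columns
#'   `variable` and `p`.
#' @param alpha strict upper bound on p.
#' @return Character vector of selected variable names (possibly empty).
#' @export
clinical_prescreen <- function(univariate, alpha = 0.5) {
  sel <- univariate$variable[univariate$p < alpha]
  if (!length(sel))
    message("no clinical variable passed the pre-screen; regression skipped")
  as.character(sel)
}

#' Run the full radiomics screening cascade
#'
#' MWU filter, variance filter, correlation filter, VIF filter, then the
#' random-forest wrapper, in that fixed order; every stage only shrinks the
#' set. The report records each dropped feature with its stage and
#' statistic, so replaying the drops reproduces the retained set.
#'
#' @param X numeric radiomics feature matrix (complete columns).
#' @param y binary labels.
#' @param cfg an [screening_config()].
#' @return An object of class `rd_screening`: list with `retained`,
#'   `stages` (per-stage retained names), `dropped` (data.frame feature /
#'   stage / statistic), `vif` and `trajectory`.
#' @export
screen_features <- function(X, y, cfg = screening_config()) {
  X <- as.matrix(X)
  stages <- list()
  dropped <- list()
  note <- function(feats, stage, stat) {
    if (length(feats))
      dropped[[length(dropped) + 1]] <<-
        data.frame(feature = feats, stage = stage, statistic = stat)
  }

  s1 <- mwu_filter(X, y, cfg$mwu_alpha)
  note(setdiff(colnames(X), s1$retained), "mwu",
       s1$p[setdiff(colnames(X), s1$retained)])
  X1 <- X[, s1$retained, drop = FALSE]
  stages$mwu <- s1$retained

  s2 <- variance_filter(X1, cfg$variance_threshold)
  note(setdiff(colnames(X1), s2$retained), "variance",
       s2$variance[setdiff(colnames(X1), s2$retained)])
  X2 <- X1[, s2$retained, drop = FALSE]
  stages$variance <- s2$retained

  s3 <- correlation_filter(X2, y, cfg$corr_threshold)
  note(s3$dropped$feature, "correlation", s3$dropped$r)
  X3 <- X2[, s3$retained, drop = FALSE]
  stages$correlation <- s3$retained

  s4 <- vif_filter(X3, cfg$vif_threshold)
  note(s4$dropped$feature, "vif", s4$dropped$vif)
  X4 <- X3[, s4$retained, drop = FALSE]
  stages$vif <- s4$retained

  s5 <- wrapper_select(X4, y, cfg)
  note(setdiff(colnames(X4), s5$retained), "wrapper", NA_real_)
  stages$wrapper <- s5$retained

  structure(list(retained = s5$retained,
                 stages = stages,
                 dropped = if (length(dropped)) do.call(rbind, dropped)
                           else data.frame(feature = character(),
                                           stage = character(),
                                           statistic = numeric()),
                 vif = s4$vif,
                 mwu_auc = s1$auc,
                 trajectory = s5$trajectory),
            class = "rd_screening")
}

#' @export
print.rd_screening <- function(x, ...) {
  sizes <- vapply(x$stages, length, numeric(1))
  cat("<rd_screening> cascade retention:\n")
  cat(sprintf("  %-12s %d\n", names(sizes), sizes), sep = "")
  cat(sprintf("final subset (%d): %s\n", length(x$retained),
              paste(utils::head(x$retained, 6), collapse = ", ")))
  invisible(x)
}
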