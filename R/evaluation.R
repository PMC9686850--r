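#' Train/validation split scheme
#'
#' Five independent stratified 70/30 splits of the full data set (one per
#' model), preserving the class ratio within one sample.
#'
#' @param n_models number of repeated splits / models.
#' @param train_fraction fraction of each class assigned to training.
#' @param seed integer seed.
#' @return An object of class `rd_split_scheme`.
#' @export
split_scheme <- function(n_models = 5, train_fraction = 0.70, seed = 1) {
  stopifnot(n_models >= 1, train_fraction > 0, train_fraction < 1)
  structure(list(n_models = as.integer(n_models),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "rd_split_scheme")
}

#' Build the stratified train/validation index pairs
#'
#' @param y binary labels.
#' @param scheme an [split_scheme()].
#' @return List of `n_models` lists with integer `train` and `validation`
#'   indices (disjoint, exhaustive, stratified).
#' @export
make_splits <- function(y, scheme = split_scheme()) {
  y <- as.integer(as.factor(y)) - 1L
  lapply(seq_len(scheme$n_models), function(m) {
    with_seed(derive_seed(scheme$seed, paste0("split", m)), {
      train <- integer(0)
      for (cls in c(0L, 1L)) {
        idx <- which(y == cls)
        n_tr <- round(scheme$train_fraction * length(idx))
        train <- c(train, sample(idx, n_tr))
      }
      train <- sort(train)
      list(train = train,
           validation = setdiff(seq_along(y), train))
    })
  })
}

#' Area under the ROC curve
#'
#' Mann-Whitney U form: the proportion of positive/negative score pairs
#' ranked concordantly, ties counted one half.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# placement values of the fast DeLong decomposition
delong_placements <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  m <- length(pos); n <- length(neg)
  v10 <- vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / n,
                numeric(1))
  v01 <- vapply(neg, function(x) (sum(pos > x) + 0.5 * sum(pos == x)) / m,
                numeric(1))
  list(v10 = v10, v01 = v01)
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric structural-component variance estimator; the Wald interval
#' `AUC +/- z * SE` is truncated to `[0, 1]`. A perfectly separating score
#' has zero estimated variance and a degenerate interval.
#'
#' @param scores numeric scores.
#' @param labels binary labels (each class needs >= 2 members).
#' @param level confidence level.
#' @return Named vector `auc`, `lower`, `upper`, `se`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  y <- as.integer(as.factor(labels)) - 1L
  m <- sum(y == 1); n <- sum(y == 0)
  if (m < 2 || n < 2) {
    warning("DeLong CI undefined with a class below 2 members")
    return(c(auc = auc(scores, labels), lower = NA, upper = NA, se = NA))
  }
  pl <- delong_placements(scores, y)
  a <- mean(pl$v10)
  s <- sqrt(var(pl$v10) / m + var(pl$v01) / n)
  z <- qnorm(1 - (1 - level) / 2)
  c(auc = a, lower = max(0, a - z * s), upper = min(1, a + z * s), se = s)
}

#' ROC curve coordinates
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return data.frame with `fpr` and `tpr`, threshold descending.
#' @export
roc_points <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(y[o] == 1); fp <- cumsum(y[o] == 0)
  data.frame(fpr = c(0, fp / max(1, sum(y == 0))),
             tpr = c(0, tp / max(1, sum(y == 1))))
}

#' Train and evaluate the 5-model scheme for one predictor set
#'
#' Selects the predictor block by `kind` (clinical variables, radiomics
#' signature, or their union), trains one GBDT per stratified 70/30 split
#' and reports train/validation AUCs with DeLong 95% intervals plus
#' per-model relative influences.
#'
#' @param radiomics numeric matrix of selected radiomics features.
#' @param clinical numeric matrix of selected clinical variables.
#' @param labels binary outcome for the same rows.
#' @param kind `"clinical"`, `"radiomics"` or `"combined"`.
#' @param scheme an [split_scheme()].
#' @param gbdt_cfg an [gbdt_config()].
#' @return An object of class `rd_eval`: list with `kind`, `models`
#'   (data.frame of AUCs and CIs), `importance` (features x models),
#'   `splits`, `roc` (per-model validation ROC points) and `features`.
#' @export
run_experiment <- function(radiomics, clinical, labels,
                           kind = c("combined", "radiomics", "clinical"),
                           scheme = split_scheme(),
                           gbdt_cfg = gbdt_config()) {
  kind <- match.arg(kind)
  X <- switch(kind,
              clinical = as.matrix(clinical),
              radiomics = as.matrix(radiomics),
              combined = cbind(as.matrix(clinical), as.matrix(radiomics)))
  y <- as.integer(as.factor(labels)) - 1L
  splits <- make_splits(y, scheme)
  rows <- list(); imps <- list(); rocs <- list()
  for (m in seq_along(splits)) {
    sp <- splits[[m]]
    cfg_m <- gbdt_cfg
    cfg_m$seed <- derive_seed(gbdt_cfg$seed, paste0(kind, "model", m))
    fit <- gbdt(X[sp$train, , drop = FALSE], y[sp$train], cfg_m)
    s_tr <- predict(fit, X[sp$train, , drop = FALSE])
    s_va <- predict(fit, X[sp$validation, , drop = FALSE])
    ci_tr <- delong_ci(s_tr, y[sp$train])
    ci_va <- delong_ci(s_va, y[sp$validation])
    rows[[m]] <- data.frame(model = m,
                            train_auc = ci_tr["auc"],
                            train_lower = ci_tr["lower"],
                            train_upper = ci_tr["upper"],
                            valid_auc = ci_va["auc"],
                            valid_lower = ci_va["lower"],
                            valid_upper = ci_va["upper"],
                            row.names = NULL)
    imps[[m]] <- gbdt_importance(fit)
    rocs[[m]] <- roc_points(s_va, y[sp$validation])
  }
  structure(list(kind = kind,
                 models = do.call(rbind, rows),
                 importance = do.call(cbind, imps),
                 splits = splits,
                 roc = rocs,
                 features = colnames(X)),
            class = "rd_eval")
}

#' @export
print.rd_eval <- function(x, ...) {
  cat(sprintf("<rd_eval> kind = %s, %d predictors, %d models\n",
              x$kind, length(x$features), nrow(x$models)))
  df <- x$models
  cat(sprintf("  model %d: train AUC %.3f (%.3f-%.3f), valid AUC %.3f (%.3f-%.3f)\n",
              df$model, df$train_auc, df$train_lower, df$train_upper,
              df$valid_auc, df$valid_lower, df$valid_upper), sep = "")
  invisible(x)
}

#' Validation ROC curves of an evaluation
#'
#' @param x an `rd_eval`.
#' @param ... passed to plot.
#' @export
plot.rd_eval <- function(x, ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, xlab = "1 - specificity",
                 ylab = "sensitivity", main = paste("ROC,", x$kind), ...)
  for (m in seq_along(x$roc))
    graphics::lines(x$roc[[m]]$fpr, x$roc[[m]]$tpr, col = m)
  invisible(x)
}
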