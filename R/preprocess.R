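#' SMOTE configuration
#'
#' @param k_neighbors number of minority nearest neighbours considered when
#'   interpolating (>= 1); clamped with a warning when the minority class is
#'   too small.
#' @param target_ratio desired minority/majority ratio in `(0, 1]`. The
#'   classic integer-amplification rule is used: each minority row spawns
#'   `k - 1` synthetic rows with
#'   `k = floor(target_ratio * n_majority / n_minority)`, so a 144/70 data
#'   set becomes 144/140 (280 rows).
#' @param seed integer seed.
#' @return An object of class `rd_smote_config`.
#' @export
smote_config <- function(k_neighbors = 5, target_ratio = 1.0, seed = 1) {
  stopifnot(k_neighbors >= 1, target_ratio > 0, target_ratio <= 1)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 target_ratio = target_ratio, seed = as.integer(seed)),
            class = "rd_smote_config")
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Generates synthetic minority rows on the segments between each minority
#' row and one of its `k` minority nearest neighbours (Euclidean distance in
#' min-max scaled space): `x_new = x_i + u * (x_nn - x_i)`, `u ~ U(0, 1)`.
#' The majority class and all original rows are untouched.
#'
#' @param X numeric matrix or data.frame of complete predictors.
#' @param y binary labels (0/1, logical or 2-level factor).
#' @param cfg an [smote_config()].
#' @param round_cols names of columns holding categorical level codes;
#'   synthetic rows are rounded back to the nearest observed code in these
#'   columns so that interpolation cannot create impossible category values.
#' @return List with the balanced `X` (matrix), `y`, and `synthetic`
#'   (logical marker of generated rows).
#' @export
smote <- function(X, y, cfg = smote_config(), round_cols = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("SMOTE requires complete numeric features")
  y <- as.integer(as.factor(y)) - 1L
  tab <- table(y)
  if (length(tab) != 2) stop("y must be binary")
  minority <- as.integer(names(tab)[which.min(tab)])
  min_idx <- which(y == minority)
  n_min <- length(min_idx); n_maj <- length(y) - n_min
  if (n_min < 2) {
    warning("single minority point: duplicating with jitter")
  }
  k_amp <- max(1L, floor(cfg$target_ratio * n_maj / n_min))
  n_new_per <- k_amp - 1L
  if (n_new_per == 0)
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))

  # neighbour search in min-max scaled space
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  S <- sweep(sweep(X[min_idx, , drop = FALSE], 2, rng[1, ]), 2, span, "/")
  k <- cfg$k_neighbors
  if (k > n_min - 1) {
    k <- max(1L, n_min - 1L)
    warning("k_neighbors clamped to minority size - 1 = ", k)
  }
  D <- as.matrix(stats::dist(S))
  diag(D) <- Inf
  ord <- apply(D, 1, function(r) order(r)[seq_len(k)])
  nn <- if (k == 1) matrix(ord, ncol = 1) else t(ord)

  with_seed(cfg$seed, {
    new_rows <- matrix(0, nrow = n_min * n_new_per, ncol = ncol(X),
                       dimnames = list(NULL, colnames(X)))
    r <- 1L
    for (ii in seq_len(n_min)) {
      xi <- X[min_idx[ii], ]
      for (s in seq_len(n_new_per)) {
        if (n_min < 2) {
          xn <- xi + stats::rnorm(length(xi), 0, 1e-6)
        } else {
          j <- nn[ii, sample.int(k, 1)]
          xn <- X[min_idx[j], ]
        }
        u <- runif(1)
        new_rows[r, ] <- xi + u * (xn - xi)
        r <- r + 1L
      }
    }
    for (cc in intersect(round_cols, colnames(X))) {
      lv <- sort(unique(X[, cc]))
      new_rows[, cc] <- vapply(new_rows[, cc],
                               function(v) lv[which.min(abs(lv - v))],
                               numeric(1))
    }
    list(X = rbind(X, new_rows),
         y = c(y, rep(minority, nrow(new_rows))),
         synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, nrow(new_rows))))
  })
}

#' Drop radiomics features containing nulls
#'
#' Removes every feature column with at least one missing value and reports
#' per-ROI retained counts (the degenerate-ROI path feeds nulls here, so the
#' report mirrors how many of the 884 features per region survive).
#'
#' @param features data.frame or matrix of radiomics features; an `id`
#'   column, if present, is preserved.
#' @return List with `features` (complete columns only) and `report`
#'   (data.frame of retained/total per ROI prefix).
#' @export
drop_null_features <- function(features) {
  id <- NULL
  if (is.data.frame(features) && "id" %in% names(features)) {
    id <- features$id
    features <- features[setdiff(names(features), "id")]
  }
  keep <- !vapply(features, anyNA, logical(1))
  kept <- features[, keep, drop = FALSE]
  roi_of <- function(nm) sub("^((PTV|SKIN)_[^_]+)_.*$", "\\1", nm)
  all_rois <- unique(roi_of(names(features)))
  report <- data.frame(
    roi = all_rois,
    total = vapply(all_rois, function(r) sum(roi_of(names(features)) == r),
                   numeric(1)),
    retained = vapply(all_rois, function(r) sum(roi_of(names(kept)) == r),
                      numeric(1)),
    row.names = NULL
  )
  if (!is.null(id)) kept <- cbind(id = id, kept, stringsAsFactors = FALSE)
  list(features = kept, report = report)
}

#' Impute missing clinical values
#'
#' Continuous columns are imputed by iterative regression (each incomplete
#' column regressed on all others under a multivariate-normal working model,
#' cycled to convergence at tolerance 1e-6, max 100 sweeps). Categorical
#' columns are imputed by chained-equation multiple imputation: `m` draws
#' from fitted multinomial (or binomial) models, combined by modal value.
#' Observed cells are never altered.
#'
#' @param table data.frame of clinical variables (factors and numerics); an
#'   `id` column is passed through.
#' @param m number of multiple-imputation draws for categorical columns.
#' @param seed integer seed.
#' @param tol convergence tolerance for the continuous sweep.
#' @param max_iter maximum sweeps.
#' @return The completed data.frame.
#' @export
impute_clinical <- function(table, m = 5, seed = 1, tol = 1e-6,
                            max_iter = 100) {
  id <- NULL
  if ("id" %in% names(table)) {
    id <- table$id
    table <- table[setdiff(names(table), "id")]
  }
  empty <- vapply(table, function(c) all(is.na(c)), logical(1))
  if (any(empty))
    stop("column(s) entirely missing: ", paste(names(table)[empty], collapse = ", "))
  frac <- vapply(table, function(c) mean(is.na(c)), numeric(1))
  if (any(frac >= 0.5))
    stop("column(s) with >= 50% missing: ",
         paste(names(table)[frac >= 0.5], collapse = ", "))

  num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  cat_cols <- setdiff(names(table), num_cols)

  # numeric design used as predictor block: categoricals as integer codes
  # with mode-filled gaps
  design <- function(tab) {
    d <- lapply(tab, function(c) {
      v <- if (is.numeric(c)) c else as.numeric(as.factor(c))
      if (anyNA(v)) {
        fill <- if (is.numeric(c)) mean(v, na.rm = TRUE)
        else as.numeric(names(which.max(table(v))))
        v[is.na(v)] <- fill
      }
      v
    })
    as.matrix(as.data.frame(d))
  }

  out <- table
  # --- continuous: iterative regression ---
  miss <- lapply(num_cols, function(cn) which(is.na(table[[cn]])))
  names(miss) <- num_cols
  inc <- num_cols[vapply(miss, length, numeric(1)) > 0]
  if (length(inc)) {
    for (cn in inc) out[[cn]][miss[[cn]]] <- mean(table[[cn]], na.rm = TRUE)
    for (it in seq_len(max_iter)) {
      delta <- 0
      for (cn in inc) {
        Xd <- design(out[setdiff(names(out), cn)])
        obs <- setdiff(seq_len(nrow(out)), miss[[cn]])
        fit <- stats::lm.fit(cbind(1, Xd[obs, , drop = FALSE]), out[[cn]][obs])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        pred <- drop(cbind(1, Xd[miss[[cn]], , drop = FALSE]) %*% beta)
        delta <- max(delta, max(abs(pred - out[[cn]][miss[[cn]]]), 0))
        out[[cn]][miss[[cn]]] <- pred
      }
      if (delta < tol) break
    }
  }

  # --- categorical: chained-equation MI, modal combination ---
  cat_inc <- cat_cols[vapply(cat_cols, function(cn) anyNA(table[[cn]]),
                             logical(1))]
  if (length(cat_inc)) {
    with_seed(seed, {
      draws <- lapply(cat_inc, function(cn) {
        mi <- which(is.na(table[[cn]]))
        yobs <- factor(table[[cn]][-mi])
        Xd <- design(out[setdiff(names(out), cn)])
        reps <- replicate(m, {
          pr <- tryCatch({
            if (nlevels(yobs) < 2) {
              matrix(1, length(mi), 1, dimnames = list(NULL, levels(yobs)))
            } else if (nlevels(yobs) == 2) {
              f <- suppressWarnings(stats::glm.fit(
                cbind(1, Xd[-mi, , drop = FALSE]),
                as.integer(yobs) - 1L,
                family = stats::binomial()))
              b <- f$coefficients; b[is.na(b)] <- 0
              p1 <- stats::plogis(drop(cbind(1, Xd[mi, , drop = FALSE]) %*% b))
              cbind(1 - p1, p1)
            } else {
              f <- nnet::multinom(yobs ~ ., data = as.data.frame(Xd[-mi, , drop = FALSE]),
                                  trace = FALSE)
              p <- predict(f, newdata = as.data.frame(Xd[mi, , drop = FALSE]),
                           type = "probs")
              if (is.null(dim(p))) p <- matrix(p, nrow = length(mi))
              p
            }
          }, error = function(e) {
            matrix(rep(prop.table(table(yobs)), each = length(mi)),
                   nrow = length(mi))
          })
          apply(pr, 1, function(pp) sample(levels(yobs), 1, prob = pmax(pp, 0)))
        })
        reps <- matrix(reps, nrow = length(mi))
        modal <- apply(reps, 1, function(r) names(which.max(table(r))))
        list(idx = mi, val = modal)
      })
      for (k in seq_along(cat_inc)) {
        cn <- cat_inc[k]
        out[[cn]][draws[[k]]$idx] <- draws[[k]]$val
      }
    })
  }
  if (!is.null(id)) out <- cbind(id = id, out, stringsAsFactors = FALSE)
  out
}

#' Encode a clinical table as a numeric model matrix
#'
#' Factors become integer level codes (single coefficient per variable, the
#' coding used in the multivariable logistic layout); numerics pass through.
#'
#' @param table clinical data.frame (an `id` column is dropped).
#' @return Numeric matrix with one column per variable.
#' @export
encode_clinical <- function(table) {
  table <- table[setdiff(names(table), "id")]
  m <- vapply(table, function(c)
    if (is.numeric(c)) c else as.numeric(as.factor(c)), numeric(nrow(table)))
  m <- matrix(m, nrow = nrow(table),
              dimnames = list(NULL, names(table)))
  attr(m, "categorical") <- names(table)[!vapply(table, is.numeric, logical(1))]
  m
}
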