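#' Univariate association tests for the clinical table
#'
#' Categorical variables use Pearson's chi-square without continuity
#' correction; when any expected cell count falls below 5 the test switches
#' to Fisher's exact test. Continuous variables use the two-sided
#' Mann-Whitney U test. Single-category variables get p = 1 with a note.
#'
#' @param table clinical data.frame (an `id` column is ignored).
#' @param labels binary outcome (0/1).
#' @param yates apply the continuity correction to chi-square (off by
#'   default).
#' @return data.frame with columns `variable`, `test`, `statistic`, `p` and
#'   `note`.
#' @export
univariate_table <- function(table, labels, yates = FALSE) {
  table <- table[setdiff(names(table), "id")]
  y <- factor(labels)
  rows <- lapply(names(table), function(v) {
    x <- table[[v]]
    if (is.numeric(x)) {
      r <- mwu_test(x, as.integer(y) - 1L == 1L)
      return(data.frame(variable = v, test = "MWU",
                        statistic = unname(r["U"]), p = unname(r["p"]),
                        note = ""))
    }
    x <- factor(x)
    if (nlevels(droplevels(x)) < 2)
      return(data.frame(variable = v, test = "none", statistic = NA_real_,
                        p = 1, note = "single category"))
    tb <- table(droplevels(x), y)
    exp <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    if (any(exp < 5)) {
      ft <- fisher.test(tb, workspace = 2e7)
      data.frame(variable = v, test = "Fisher", statistic = NA_real_,
                 p = ft$p.value, note = "expected count < 5")
    } else {
      ct <- suppressWarnings(chisq.test(tb, correct = yates))
      data.frame(variable = v, test = "chi-square",
                 statistic = unname(ct$statistic), p = ct$p.value, note = "")
    }
  })
  do.call(rbind, rows)
}

#' Multivariable logistic regression (Newton-Raphson)
#'
#' Maximum-likelihood logistic fit by Newton-Raphson with step halving,
#' tolerance 1e-8 on the coefficient change, at most `max_iter` iterations.
#' Reports per-variable coefficients, Wald Z and two-sided p-values.
#' Quasi-complete separation is detected (runaway coefficients) and flagged,
#' with coefficients capped.
#'
#' @param X numeric predictor matrix (no intercept column; one is added).
#' @param y binary outcome (0/1).
#' @param variables optional subset of column names to use.
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance.
#' @return An object of class `rd_logit`: list with `coefficients`
#'   (data.frame variable / coefficient / z / p), `converged`, `separation`,
#'   `deviance_trace` and `n`.
#' @export
fit_logistic <- function(X, y, variables = NULL, max_iter = 50, tol = 1e-8) {
  X <- as.matrix(X)
  if (!is.null(variables)) X <- X[, variables, drop = FALSE]
  y <- as.integer(as.factor(y)) - 1L
  n <- nrow(X)
  if (n <= ncol(X) + 1) stop("need n > number of variables + 1")
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  beta <- rep(0, p)
  dev <- function(b) {
    eta <- drop(Xd %*% b)
    lse <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
    -2 * sum(y * eta - lse)
  }
  trace <- dev(beta)
  converged <- FALSE
  cap <- 15
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    H <- crossprod(Xd, Xd * W) + diag(1e-10, p)
    score <- crossprod(Xd, y - mu)
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) break
    # step halving keeps the deviance monotone
    lam <- 1
    repeat {
      cand <- beta + lam * drop(step)
      if (dev(cand) <= trace[length(trace)] + 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    beta_new <- beta + lam * drop(step)
    trace <- c(trace, dev(beta_new))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  separation <- any(abs(beta) > cap)
  if (separation) {
    beta <- pmin(pmax(beta, -cap), cap)
    converged <- FALSE
  }
  eta <- drop(Xd %*% beta)
  mu <- plogis(eta)
  W <- pmax(mu * (1 - mu), 1e-10)
  H <- crossprod(Xd, Xd * W)
  se <- sqrt(diag(tryCatch(solve(H), error = function(e) diag(Inf, p))))
  z <- beta / se
  structure(list(
    coefficients = data.frame(variable = colnames(Xd),
                              coefficient = unname(beta),
                              z = unname(z),
                              p = unname(2 * pnorm(-abs(z))),
                              row.names = NULL),
    converged = converged,
    separation = separation,
    deviance_trace = trace,
    n = n), class = "rd_logit")
}

#' @export
print.rd_logit <- function(x, ...) {
  cat(sprintf("<rd_logit> n = %d, deviance = %.3f, converged = %s%s\n",
              x$n, x$deviance_trace[length(x$deviance_trace)],
              x$converged,
              if (x$separation) " (separation detected)" else ""))
  df <- x$coefficients
  df$coefficient <- round(df$coefficient, 4)
  df$z <- round(df$z, 2)
  df$p <- signif(df$p, 4)
  names(df) <- c("Variable", "Coefficient", "Wald Z", "Pr(>|Z|)")
  print(df, row.names = FALSE)
  invisible(x)
}
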