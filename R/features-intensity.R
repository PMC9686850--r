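# Intensity families: direct statistics on raw HU (global + local-window),
# histogram statistics and histogram Gaussian-mixture fits.

moment_skewness <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

moment_kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^4) / m2^2
}

hist_probs <- function(x, nbins = 64) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(1)
  b <- pmin(nbins, floor((x - rng[1]) / (rng[2] - rng[1]) * nbins) + 1)
  tabulate(b, nbins) / length(x)
}

hist_entropy <- function(x, nbins = 64) {
  p <- hist_probs(x, nbins)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Intensity direct features
#'
#' 21 global statistics of the raw in-mask HU values plus 35 local features:
#' each of 7 local statistics (mean, std, range, entropy, median, min, max)
#' is evaluated on the in-mask window of radius `local_window` around every
#' voxel and then aggregated by max, min, mean, median and std. Quantiles use
#' the type-7 rule; entropy uses a 64-bin min-max histogram.
#'
#' @param image numeric 3-D array of raw HU.
#' @param mask logical array.
#' @param local_window window voxel radius (1 means a 3x3x3 window).
#' @return Named numeric vector of 56 values (all `NA` for an empty mask).
#' @export
intensity_direct_features <- function(image, mask, local_window = 1) {
  nm <- c(paste0("ID_", ID_GLOBAL_STATS),
          as.vector(t(outer(ID_LOCAL_STATS, ID_LOCAL_AGGS,
                            function(s, a) paste0("ID_Local", s, a)))))
  if (!any(mask)) return(setNames(rep(NA_real_, 56), nm))
  x <- image[mask]
  q <- quantile(x, c(0.025, 0.10, 0.25, 0.75, 0.90, 0.975), type = 7,
                names = FALSE)
  glob <- c(mean(x), median(x), min(x), max(x), diff(range(x)),
            sd(x), var(x), moment_skewness(x), moment_kurtosis(x),
            sum(x^2), hist_entropy(x), mean(abs(x - mean(x))),
            sqrt(mean(x^2)), sum(hist_probs(x)^2),
            q[2], q[3], q[4], q[5], q[4] - q[3], q[1], q[6])
  if (length(x) == 1) { glob[6] <- 0; glob[7] <- 0 }

  lev <- discretize(image, mask, 64)
  ls <- cpp_local_stats(as.numeric(image), as.integer(lev),
                        as.integer(dim(image)), 64L, as.integer(local_window))
  aggs <- apply(ls, 2, function(v)
    c(max(v), min(v), mean(v), median(v), if (length(v) > 1) sd(v) else 0))
  # aggs is 5 x 7 (agg x stat); flatten stat-major to match the name order
  local <- as.vector(aggs)
  setNames(c(glob, local), nm)
}

#' Intensity histogram features
#'
#' 40 statistics of the in-mask intensity distribution: 21 quantiles (type-7)
#' at probabilities 0.025, 0.05..0.95, 0.975, plus mean, median, mode (64-bin
#' histogram mode midpoint), SD, MAD (median absolute deviation), robust MAD
#' (1.4826-scaled), skewness, kurtosis, energy, entropy, uniformity, range,
#' IQR, coefficient of variation, quartile coefficient of dispersion, min,
#' max, sum and count.
#'
#' @inheritParams intensity_direct_features
#' @return Named numeric vector of 40 values.
#' @export
intensity_histogram_features <- function(image, mask) {
  nm <- c(paste0("GOH", fmt_prob(GOH_PROBS), "Quantile"),
          paste0("GOH_", GOH_STATS))
  if (!any(mask)) return(setNames(rep(NA_real_, 40), nm))
  x <- image[mask]
  qs <- quantile(x, GOH_PROBS, type = 7, names = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    mode <- rng[1]
  } else {
    p <- hist_probs(x)
    mids <- rng[1] + (seq_along(p) - 0.5) * diff(rng) / length(p)
    mode <- mids[which.max(p)]
  }
  madv <- median(abs(x - median(x)))
  q1 <- quantile(x, 0.25, type = 7, names = FALSE)
  q3 <- quantile(x, 0.75, type = 7, names = FALSE)
  stats <- c(mean(x), median(x), mode,
             if (length(x) > 1) sd(x) else 0,
             madv, 1.4826 * madv,
             moment_skewness(x), moment_kurtosis(x),
             sum(x^2), hist_entropy(x), sum(hist_probs(x)^2),
             diff(rng), q3 - q1,
             if (mean(x) != 0) sd(x) / mean(x) else 0,
             if ((q3 + q1) != 0) (q3 - q1) / (q3 + q1) else 0,
             rng[1], rng[2], sum(x), length(x))
  if (length(x) == 1) stats[14] <- 0
  setNames(c(qs, stats), nm)
}

fit_gauss_mixture <- function(mids, dens, x, k) {
  # least-squares fit of a k-component Gaussian mixture to the binned density
  qs <- quantile(x, (seq_len(k) - 0.5) / k, names = FALSE)
  s0 <- max(sd(x) / k, diff(range(x)) / 50, 1e-6)
  start <- list()
  for (j in seq_len(k)) {
    start[[paste0("m", j)]] <- qs[j]
    start[[paste0("s", j)]] <- s0
    start[[paste0("a", j)]] <- max(dens) / k * s0 * sqrt(2 * pi)
  }
  form <- paste0("dens ~ ",
                 paste(sprintf("a%d / (s%d * sqrt(2*pi)) * exp(-0.5*((mids - m%d)/s%d)^2)",
                               seq_len(k), seq_len(k), seq_len(k), seq_len(k)),
                       collapse = " + "))
  lower <- unlist(lapply(seq_len(k), function(j)
    c(min(x) - diff(range(x)), 1e-8, 0)))
  upper <- unlist(lapply(seq_len(k), function(j)
    c(max(x) + diff(range(x)), diff(range(x)) * 2, Inf)))
  fit <- tryCatch(
    minpack.lm::nlsLM(stats::as.formula(form),
                      data = data.frame(mids = mids, dens = dens),
                      start = start, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  comps <- t(vapply(seq_len(k), function(j)
    c(mean = cf[[paste0("m", j)]], std = cf[[paste0("s", j)]],
      amplitude = cf[[paste0("a", j)]] / (cf[[paste0("s", j)]] * sqrt(2 * pi))),
    numeric(3)))
  comps[order(comps[, "mean"]), , drop = FALSE]
}

#' Histogram Gaussian-fit features
#'
#' Least-squares fits of 1-, 2- and 3-component Gaussian mixtures to the
#' 64-bin density histogram of in-mask HU. Per component the mean, standard
#' deviation and amplitude (density peak height) are reported, components
#' sorted by mean. Fits require at least 50 voxels; a non-converged fit
#' yields `NA`s for its components. Zero-variance data give std 0 and the
#' full bin mass as amplitude of the first component.
#'
#' @inheritParams intensity_direct_features
#' @param components integer vector of mixture sizes to fit.
#' @return Named numeric vector (18 values for components 1:3).
#' @export
gaussfit_features <- function(image, mask, components = 1:3) {
  nm <- sub("^F6\\.", "", gaussfit_names(components))
  n_out <- sum(3 * components)
  if (sum(mask) < 50) return(setNames(rep(NA_real_, n_out), nm))
  x <- image[mask]
  out <- numeric(0)
  if (diff(range(x)) == 0) {
    for (k in components) {
      vals <- c(x[1], 0, 1, rep(c(x[1], 0, 0), k - 1))
      out <- c(out, vals)
    }
    return(setNames(out, nm))
  }
  br <- seq(min(x), max(x), length.out = 65)
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  for (k in components) {
    comps <- fit_gauss_mixture(h$mids, h$density, x, k)
    if (is.null(comps)) out <- c(out, rep(NA_real_, 3 * k))
    else out <- c(out, as.vector(t(comps)))
  }
  setNames(out, nm)
}
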