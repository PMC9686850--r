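# Independent brute-force oracles used across the test files. These are
# deliberately naive (loops, enumeration) and share no code with the
# package internals they check.

# --- texture matrix oracles (per-slice accumulation, 2.5D) ---

oracle_glcm_counts <- function(levels, dxy, step) {
  d <- dim(levels)
  G <- max(levels)
  M <- matrix(0, G, G)
  for (z in seq_len(d[3])) {
    for (y in seq_len(d[2])) {
      for (x in seq_len(d[1])) {
        a <- levels[x, y, z]
        if (a == 0) next
        x2 <- x + dxy[1] * step
        y2 <- y + dxy[2] * step
        if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2]) next
        b <- levels[x2, y2, z]
        if (b == 0) next
        M[a, b] <- M[a, b] + 1
      }
    }
  }
  M
}

oracle_glrlm_counts <- function(levels, dxy) {
  d <- dim(levels)
  G <- max(levels)
  M <- matrix(0, G, max(d[1], d[2]))
  for (z in seq_len(d[3])) {
    # enumerate all maximal lines along dxy in this slice
    starts <- list()
    for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
      px <- x - dxy[1]; py <- y - dxy[2]
      if (px >= 1 && px <= d[1] && py >= 1 && py <= d[2]) next
      starts[[length(starts) + 1]] <- c(x, y)
    }
    for (s in starts) {
      x <- s[1]; y <- s[2]
      line <- integer(0)
      while (x >= 1 && x <= d[1] && y >= 1 && y <= d[2]) {
        line <- c(line, levels[x, y, z])
        x <- x + dxy[1]; y <- y + dxy[2]
      }
      # runs of equal non-zero values
      r <- rle(line)
      for (k in seq_along(r$values)) {
        v <- r$values[k]
        if (v != 0) M[v, r$lengths[k]] <- M[v, r$lengths[k]] + 1
      }
    }
  }
  M
}

oracle_ngtdm_tables <- function(levels) {
  d <- dim(levels)
  G <- max(levels)
  s <- numeric(G); n <- numeric(G)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    v <- levels[x, y, z]
    if (v == 0) next
    nb <- c()
    for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0) next
      x2 <- x + dx; y2 <- y + dy
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2]) next
      w <- levels[x2, y2, z]
      if (w != 0) nb <- c(nb, w)
    }
    if (!length(nb)) next
    s[v] <- s[v] + abs(v - mean(nb))
    n[v] <- n[v] + 1
  }
  list(s = s, n = n)
}

# direction in degrees -> unit in-plane step
oracle_dir <- function(deg) {
  rad <- deg * pi / 180
  c(round(cos(rad)), round(sin(rad)))
}

# --- DeLong variance oracle: O(n^2) double loop ---

oracle_delong_var <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  m <- length(pos); n <- length(neg)
  psi <- function(xp, xn) (xp > xn) + 0.5 * (xp == xn)
  v10 <- numeric(m); v01 <- numeric(n)
  for (i in seq_len(m)) v10[i] <- mean(vapply(neg, function(b) psi(pos[i], b), 1))
  for (j in seq_len(n)) v01[j] <- mean(vapply(pos, function(a) psi(a, neg[j]), 1))
  var(v10) / m + var(v01) / n
}

# --- straight-line GBDT oracle: Eqs for loss, gradient, leaf value, with
#     exhaustive depth-1 tree search ---

oracle_gbdt_stump <- function(X, y, M, nu) {
  y <- ifelse(y > 0, 1, -1)
  f0 <- log(sum(y == 1) / sum(y == -1))
  f <- rep(f0, nrow(X))
  stumps <- list()
  for (m in seq_len(M)) {
    r <- y / (1 + exp(y * f))
    best <- NULL
    for (j in seq_len(ncol(X))) {
      xs <- sort(unique(X[, j]))
      if (length(xs) < 2) next
      for (t in (xs[-length(xs)] + xs[-1]) / 2) {
        L <- X[, j] < t
        if (!any(L) || all(L)) next
        sse <- sum((r[L] - mean(r[L]))^2) + sum((r[!L] - mean(r[!L]))^2)
        red <- sum((r - mean(r))^2) - sse
        if (is.null(best) || red > best$red + 1e-12) {
          best <- list(j = j, t = t, red = red)
        }
      }
    }
    if (is.null(best)) break
    L <- X[, best$j] < best$t
    cL <- sum(r[L]) / sum(abs(r[L]) * (1 - abs(r[L])))
    cR <- sum(r[!L]) / sum(abs(r[!L]) * (1 - abs(r[!L])))
    f <- f + nu * ifelse(L, cL, cR)
    stumps[[m]] <- best
  }
  list(f = f, f0 = f0, stumps = stumps)
}

# --- small fixtures ---

tiny_cohort <- function(n = 12, pos = 8, delta = 1, seed = 3,
                        grid = c(24, 24, 16)) {
  generate_cohort(cohort_spec(n_patients = n, n_rd2plus = pos,
                              grid_shape = grid, effect_size_delta = delta,
                              seed = seed))
}

# random gray-level toy volume with an irregular mask
toy_levels <- function(dim3 = c(8, 8, 3), G = 4, seed = 42, p_mask = 0.8) {
  set.seed(seed)
  lev <- array(sample.int(G, prod(dim3), replace = TRUE), dim = dim3)
  msk <- array(runif(prod(dim3)) < p_mask, dim = dim3)
  lev[!msk] <- 0L
  storage.mode(lev) <- "integer"
  lev
}
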