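# Independent brute-force oracles used to validate the fast implementations.

# Lower convex hull baseline by exhaustive chord search: a chord through two
# data points is a valid minorant if no data point lies below it; the lower
# convex envelope at each x is the maximum over all valid chords (clamped to
# pass through the endpoints). O(n^3).
oracle_rubberband <- function(x, y) {
  n <- length(x)
  base <- rep(-Inf, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      slope <- (y[j] - y[i]) / (x[j] - x[i])
      line <- y[i] + slope * (x - x[i])
      if (all(y - line >= -1e-9 * max(1, abs(y)))) {
        seg <- x >= x[i] & x <= x[j]
        base[seg] <- pmax(base[seg], line[seg])
      }
    }
  }
  base[1] <- y[1]; base[n] <- y[n]
  base
}

# Savitzky-Golay by direct per-window weighted least squares: fit a
# polynomial of the given order to the window centred on each interior
# point and evaluate its deriv-th derivative at the centre.
oracle_savgol <- function(y, h, window, polyorder, deriv) {
  n <- length(y)
  half <- (window - 1) / 2
  out <- rep(NA_real_, n)
  for (i in (half + 1):(n - half)) {
    idx <- (i - half):(i + half)
    t_local <- (idx - i) * h
    fit <- lm(y[idx] ~ poly(t_local, polyorder, raw = TRUE))
    out[i] <- coef(fit)[deriv + 1] * factorial(deriv)
  }
  out
}

# Kennard-Stone selection order, recomputing every pairwise distance at
# every step from scratch.
oracle_kennard_stone <- function(x) {
  n <- nrow(x)
  dfun <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  best <- c(1L, 2L); best_d <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (dfun(i, j) > best_d) { best_d <- dfun(i, j); best <- c(i, j) }
  sel <- sort(best)
  while (length(sel) < n) {
    rem <- setdiff(1:n, sel)
    md <- sapply(rem, function(r) min(sapply(sel, function(s) dfun(r, s))))
    sel <- c(sel, rem[which.max(md)])
  }
  sel
}

# Two-class Fisher discriminant direct on raw features (no PCA), for
# full-rank toy problems: w = Sw^-1 (m1 - m2), oriented so the first
# class projects higher.
oracle_fisher_projection <- function(x, labels) {
  classes <- unique(labels)
  a <- x[labels == classes[1], , drop = FALSE]
  b <- x[labels == classes[2], , drop = FALSE]
  sw <- (crossprod(sweep(a, 2, colMeans(a))) +
         crossprod(sweep(b, 2, colMeans(b)))) / (nrow(x) - 2)
  w <- solve(sw, colMeans(a) - colMeans(b))
  proj <- as.numeric(x %*% w)
  if (mean(proj[labels == classes[1]]) < mean(proj[labels == classes[2]]))
    proj <- -proj
  proj
}

# Monte-Carlo power of a two-tailed Welch t-test with equal group sizes.
oracle_mc_power <- function(n, d, alpha = 0.05, nsim = 1e5) {
  a <- matrix(rnorm(n * nsim), n)
  b <- matrix(rnorm(n * nsim, mean = d), n)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums(sweep(a, 2, ma)^2) / (n - 1)
  vb <- colSums(sweep(b, 2, mb)^2) / (n - 1)
  se2 <- va / n + vb / n
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / n)^2 / (n - 1) + (vb / n)^2 / (n - 1))
  mean(abs(tt) > qt(1 - alpha / 2, df))
}
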