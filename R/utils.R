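# Seed handling: set a temporary RNG state, returning the previous state
# so callers can restore it (keeps package functions from perturbing the
# caller's random stream).
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Derived sub-seed: deterministic, stays inside 32-bit integer range.
sub_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483647)
}

# Vectorised two-sample Welch t-test over the columns of two matrices.
# Returns a list of t statistics, Welch-Satterthwaite dfs and two-tailed
# p-values (one per column).
welch_columns <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums(sweep(a, 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(b, 2, mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t_stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  # degenerate columns (both variances zero, e.g. baseline anchor points
  # pinned to zero in every spectrum): no evidence either way unless the
  # constants differ
  degen <- se2 == 0
  if (any(degen)) {
    p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
    t_stat[degen] <- ifelse(ma[degen] == mb[degen], 0, Inf)
  }
  list(t = t_stat, df = df, p = p, mean_diff = ma - mb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
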