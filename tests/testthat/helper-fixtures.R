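# Small in-code fixtures shared across test files.

fp_axis <- function() seq(900, 1800, by = 4)

tiny_meta <- function(n, group = "HC", subgroup = "none_assigned",
                      biofluid = "serum", subject = NULL) {
  data.frame(subject_id = subject %||% sprintf("s%02d", seq_len(n)),
             group = rep(group, length.out = n),
             subgroup = rep(subgroup, length.out = n),
             biofluid = rep(biofluid, length.out = n),
             spot = rep(1L, n), replicate = rep(1L, n),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# n subjects per group, r replicates each, gaussian band spectra with an
# optional class effect at one band; small axis for speed
tiny_two_class <- function(n_per_group = 6, r = 4, effect_at = 1304,
                           delta = 0.05, noise = 0.01, seed = 42,
                           axis = seq(1000, 1600, by = 4)) {
  set.seed(seed)
  centers <- c(1100, 1304, 1500)
  width <- c(15, 12, 20)
  base <- c(0.3, 0.2, 0.25)
  g <- exp(-(outer(centers, axis, `-`) / width)^2 / 2)
  rows <- list(); meta <- list()
  k <- 0
  for (grp in c("HC", "CVID")) for (i in seq_len(n_per_group)) {
    k <- k + 1
    amp <- base + rnorm(3, 0, noise)
    if (grp == "CVID" && !is.null(effect_at))
      amp[centers == effect_at] <- amp[centers == effect_at] + delta
    for (rep_i in seq_len(r)) {
      rows[[length(rows) + 1]] <-
        as.numeric(amp %*% g) + rnorm(length(axis), 0, noise / 4)
      meta[[length(meta) + 1]] <- data.frame(
        subject_id = sprintf("%s_%02d", grp, i), group = grp,
        subgroup = if (grp == "CVID") "complications" else "none_assigned",
        biofluid = "serum", spot = 1L, replicate = rep_i,
        stringsAsFactors = FALSE)
    }
  }
  spectral_dataset(axis, do.call(rbind, rows), do.call(rbind, meta))
}

expect_setequal_chr <- function(a, b) testthat::expect_setequal(a, b)
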