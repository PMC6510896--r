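test_that("the t-test track is subject-level and localises an implanted shift", {
  ds <- tiny_two_class(n_per_group = 8, r = 4, effect_at = 1304,
                       delta = 0.06, seed = 21)
  pp <- apply_recipe(ds, preprocess_recipe("rubberband"))
  tr <- ttest_track(pp)
  expect_length(tr$score, length(pp$wavenumbers))
  expect_true(all(tr$score >= 0))
  expect_lte(abs(tr$wavenumbers[which.max(tr$score)] - 1304), 8)

  # p-values computed on n = subjects: a dataset whose replicates are
  # exact copies of the subject mean must give the identical track
  avg <- average_replicates(pp)
  dup <- subset_spectra(avg, rep(seq_len(nrow(avg$meta)), each = 3))
  dup$meta$replicate <- rep(1:3, nrow(avg$meta))
  tr_dup <- ttest_track(dup)
  expect_equal(tr_dup$score, tr$score, tolerance = 1e-10)

  # invariant to replicate ordering and class relabeling
  set.seed(2)
  perm <- sample(nrow(pp$absorbance))
  tr_perm <- ttest_track(subset_spectra(pp, perm))
  expect_equal(tr_perm$score, tr$score, tolerance = 1e-10)
  relab <- ttest_track(pp$absorbance, labels = pp$meta$group,
                       subjects = pp$meta$subject_id)
  expect_equal(relab$score, tr$score, tolerance = 1e-10)

  expect_error(ttest_track(subset_spectra(pp, pp$meta$group == "HC")),
               "2 classes")
})

test_that("forward feature selection finds a single informative wavenumber", {
  set.seed(33)
  n <- 12; p <- 40
  x <- matrix(rnorm(2 * n * p, 0, 0.1), 2 * n, p)
  colnames(x) <- seq(1000, by = 4, length.out = p)
  x[(n + 1):(2 * n), 17] <- x[(n + 1):(2 * n), 17] + 1  # informative column
  lab <- rep(c("HC", "CVID"), each = n)
  tr <- ffs_track(x, labels = lab, subjects = sprintf("s%02d", 1:(2 * n)),
                  rounds = 100, seed = 9)
  expect_gte(tr$score[17], 95)
  # counting bounds
  expect_true(all(tr$score <= 100))
  expect_lte(sum(tr$score), 6 * 100)
  expect_error(ffs_track(x, lab, rounds = 0), "rounds")
})

test_that("FFS selection under the null never mimics a real effect", {
  ds0 <- tiny_two_class(n_per_group = 10, r = 2, effect_at = NULL, seed = 44)
  pp0 <- apply_recipe(average_replicates(ds0), preprocess_recipe("rubberband"))
  tr0 <- ffs_track(pp0, rounds = 60, seed = 3)
  ds1 <- tiny_two_class(n_per_group = 10, r = 2, effect_at = 1304,
                        delta = 0.06, seed = 44)
  pp1 <- apply_recipe(average_replicates(ds1), preprocess_recipe("rubberband"))
  tr1 <- ffs_track(pp1, rounds = 60, seed = 3)
  at_band <- abs(tr1$wavenumbers - 1304) <= 8
  # with the effect, the band is selected nearly every round (counts may
  # split over adjacent axis points of the band); without, rarely
  expect_gte(sum(tr1$score[at_band]), 0.9 * 60)
  expect_lte(max(tr0$score[at_band]), 0.5 * 60)
})

test_that("peak detection ranks, separates and handles degenerate tracks", {
  wn <- seq(1000, 1400, by = 4)
  mk <- function(score) structure(list(method = "ttest", wavenumbers = wn,
                                       score = score),
                                  class = "feature_track")
  # six well-separated triangles
  s <- numeric(length(wn))
  tops <- c(1040, 1100, 1160, 1220, 1280, 1340)
  hts <- c(6, 5, 4, 3, 2, 1)
  for (i in seq_along(tops)) {
    j <- which(wn == tops[i])
    s[(j - 2):(j + 2)] <- hts[i] * c(0.3, 0.6, 1, 0.6, 0.3)
  }
  pk <- detect_peaks(mk(s))
  expect_equal(pk$peaks$wavenumber, tops)
  expect_equal(pk$peaks$score, hts)

  # two maxima 8 cm-1 apart: only the higher survives
  s2 <- numeric(length(wn))
  s2[wn == 1100] <- 5; s2[wn == 1108] <- 3
  pk2 <- detect_peaks(mk(s2))
  expect_equal(pk2$peaks$wavenumber, 1100)
  expect_equal(pk2$omitted$wavenumber, 1108)
  # but 12 cm-1 apart both survive
  s3 <- numeric(length(wn))
  s3[wn == 1100] <- 5; s3[wn == 1112] <- 3
  expect_equal(sort(detect_peaks(mk(s3))$peaks$wavenumber), c(1100, 1112))

  # monotone track: single endpoint maximum
  pk4 <- detect_peaks(mk(seq_along(wn)))
  expect_equal(pk4$peaks$wavenumber, max(wn))
  # plateau takes its lowest-wavenumber point
  s5 <- numeric(length(wn)); s5[wn >= 1100 & wn <= 1112] <- 2
  expect_equal(detect_peaks(mk(s5))$peaks$wavenumber, 1100)
  # at most k peaks
  expect_lte(nrow(detect_peaks(mk(s), k = 3)$peaks), 3)
})

test_that("panel merging flags corroboration and filters across methods", {
  wn <- seq(1000, 1400, by = 4)
  mk <- function(method, at, score) {
    s <- numeric(length(wn)); s[match(at, wn)] <- score
    detect_peaks(structure(list(method = method, wavenumbers = wn, score = s),
                           class = "feature_track"))
  }
  p1 <- mk("ttest", c(1100, 1200), c(5, 4))
  p2 <- mk("cluster_vector", c(1100, 1300), c(3, 2))
  p3 <- mk("ffs", c(1100, 1204), c(7, 6))
  merged <- merge_panels(list(p1, p2, p3))
  at_1100 <- merged$peaks[merged$peaks$wavenumber == 1100, ]
  expect_equal(at_1100$n_methods, 3)
  expect_true(at_1100$corroborated)
  # 1200 (ttest) and 1204 (ffs) are within 10: the higher-scoring 1204 wins
  expect_true(1204 %in% merged$peaks$wavenumber)
  expect_false(1200 %in% merged$peaks$wavenumber)
  expect_equal(merged$omitted$wavenumber, 1200)
  d <- diff(sort(merged$peaks$wavenumber))
  expect_true(all(d > 10))
  # empty input
  empty <- merge_panels(list())
  expect_equal(nrow(empty$peaks), 0)
})

test_that("subject-level intensity analysis reports direction, CI and subject n", {
  sim <- simulate_spectra(sim_config(n_hc = 12, n_cvid_non = 4,
                                     n_cvid_comp = 8, seed = 51,
                                     axis = seq(900, 1800, by = 4)))
  pp <- select_region(apply_recipe(sim$dataset, preprocess_recipe("rubberband")),
                      "fingerprint")
  cmp <- subject_intensity_analysis(pp, c(1034, 1528))
  hc_cvid <- cmp[cmp$group_a == "HC" & cmp$group_b == "CVID", ]
  expect_equal(hc_cvid$n_a, c(12, 12))
  expect_equal(hc_cvid$n_b, c(12, 12))
  i1034 <- hc_cvid[hc_cvid$wavenumber == 1034, ]
  expect_lt(i1034$p_value, 0.05)
  expect_identical(i1034$direction, "up_in_CVID")
  expect_identical(hc_cvid$direction[hc_cvid$wavenumber == 1528],
                   "down_in_CVID")
  # CI contains the point estimate
  expect_true(all(cmp$ci_lower <= cmp$diff + 1e-12 &
                  cmp$diff <= cmp$ci_upper + 1e-12))
  expect_error(subject_intensity_analysis(pp, 1034,
                                          contrasts = list(c("HC", "sick"))),
               "unknown group")
})

test_that("null-data intensity comparisons cover zero at the nominal rate", {
  cover <- logical(20)
  for (i in 1:20) {
    sim <- simulate_spectra(null_variant(
      sim_config(n_hc = 8, n_cvid_non = 3, n_cvid_comp = 5, seed = 600 + i,
                 axis = seq(900, 1400, by = 4))))
    pp <- apply_recipe(sim$dataset, preprocess_recipe("rubberband"))
    cmp <- subject_intensity_analysis(pp, 1034,
                                      contrasts = list(c("HC", "CVID")))
    cover[i] <- cmp$ci_lower <= 0 && 0 <= cmp$ci_upper
  }
  expect_gte(mean(cover), 0.75)  # 95% nominal, 20 draws
})

test_that("minimum-n power search is minimal, monotone and matches power.t.test", {
  pr <- power_min_n(0, 1, 1, 1)
  expect_gte(pr$achieved_power, 0.80)
  expect_lt(pr$power_at_n_minus_1, 0.80)
  # equal-n, equal-sd case agrees with the closed-form routine
  want <- ceiling(stats::power.t.test(delta = 1, sd = 1, power = 0.8)$n)
  expect_equal(pr$n_b, want)
  # larger effects never need more subjects
  ns <- sapply(c(0.5, 1, 1.5, 2), function(d) power_min_n(0, 1, d, 1)$n_b)
  expect_true(all(diff(ns) <= 0))
  # unequal allocation respects the ratio
  pr2 <- power_min_n(0, 1, 1, 1, ratio = 2)
  expect_equal(pr2$n_a, 2 * pr2$n_b)
  expect_error(power_min_n(1, 1, 1, 1), "equal")
  expect_error(power_min_n(0, 0, 1, 1), "positive")
})
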