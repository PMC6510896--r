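test_that("PCA satisfies its algebraic contract", {
  set.seed(2)
  x <- matrix(rnorm(80), 10, 8)
  p <- pca_fit(x)
  # orthonormal loadings
  expect_equal(p$loadings %*% t(p$loadings), diag(nrow(p$loadings)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # diagonal score covariance
  cv <- cov(p$scores)
  expect_equal(cv, diag(diag(cv)), tolerance = 1e-8, ignore_attr = TRUE)
  # ordered, summing to <= 1
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-12)
  # full reconstruction of centred data
  rec <- p$scores %*% p$loadings
  expect_equal(rec, sweep(x, 2, p$mean), tolerance = 1e-8, ignore_attr = TRUE)
  # reconstruction error non-increasing in the number of PCs
  errs <- sapply(1:5, function(k) {
    pk <- pca_fit(x, k)
    sum((sweep(x, 2, pk$mean) - pk$scores %*% pk$loadings)^2)
  })
  expect_true(all(diff(errs) <= 1e-8))
  expect_error(pca_fit(x, 40), "n_pcs")
})

test_that("PCA matches a covariance-eigendecomposition oracle", {
  set.seed(9)
  x <- matrix(rnorm(80), 10, 8)
  p <- pca_fit(x)
  eig <- eigen(cov(x), symmetric = TRUE)
  k <- nrow(p$loadings)
  expect_equal(p$explained, (eig$values / sum(eig$values))[1:k],
               tolerance = 1e-8)
  for (j in 1:k) {
    v <- eig$vectors[, j]
    # same axis up to sign
    expect_equal(abs(sum(p$loadings[j, ] * v)), 1, tolerance = 1e-8)
  }
  # rank-1 data: first PC carries all the variance
  r1 <- outer(1:6, rnorm(8)) + matrix(5, 6, 8)
  expect_equal(pca_fit(r1, 1)$explained, 1, tolerance = 1e-10)
  # deterministic sign convention: refit agrees exactly
  expect_identical(p$loadings, pca_fit(x)$loadings)
})

test_that("PCA-LDA reproduces direct Fisher LDA on full-rank toys", {
  set.seed(4)
  for (rep_i in 1:5) {
    x <- rbind(matrix(rnorm(16, 0), 8, 2), matrix(rnorm(16, 1.5), 8, 2))
    lab <- rep(c("HC", "CVID"), each = 8)
    fit <- pcalda(x, lab, subjects = sprintf("s%02d", 1:16), n_pcs = 2,
                  cv = FALSE)
    want <- oracle_fisher_projection(x, lab)
    # same discriminant axis: perfectly correlated projections
    expect_equal(abs(cor(fit$ld1, want)), 1, tolerance = 1e-8)
    # documented orientation: lexicographically first class (CVID) positive
    expect_gt(mean(fit$ld1[lab == "CVID"]), mean(fit$ld1[lab == "HC"]))
    # and agreement with MASS::lda scalings up to scale/sign
    ml <- MASS::lda(x, grouping = lab)
    proj <- as.numeric(scale(x, center = TRUE, scale = FALSE) %*% ml$scaling)
    expect_equal(abs(cor(fit$ld1, proj)), 1, tolerance = 1e-8)
  }
})

test_that("cross-validated scores separate implanted classes and respect subjects", {
  ds <- tiny_two_class(n_per_group = 8, r = 3, delta = 0.08, seed = 10)
  pp <- apply_recipe(ds, preprocess_recipe("rubberband"))
  fit <- pcalda(pp)
  expect_lt(fit$cv_p_value, 1e-6)
  # manual refit of one fold must reproduce the held-out scores exactly
  s <- unique(pp$meta$subject_id)[1]
  hold <- pp$meta$subject_id == s
  refit <- pcalda(pp$absorbance[!hold, ], pp$meta$group[!hold],
                  pp$meta$subject_id[!hold], cv = FALSE)
  sc <- predict(refit, pp$absorbance[hold, , drop = FALSE])
  expect_equal(unname(fit$cv_ld1[hold]), unname(sc), tolerance = 1e-10)
  # class with a single subject cannot be cross-validated
  expect_error(pcalda(pp$absorbance[1:6, ], c("A", "A", "A", "B", "B", "B"),
                      subjects = c("x", "x", "x", "y", "y", "y")),
               "2 subjects")
})

test_that("PCA-LDA is invariant to replicate order and global scaling", {
  ds <- tiny_two_class(n_per_group = 5, r = 3, seed = 12)
  pp <- apply_recipe(ds, preprocess_recipe("rubberband"))
  fit <- pcalda(pp, cv = FALSE)
  set.seed(1)
  perm <- sample(nrow(pp$absorbance))
  fit_p <- pcalda(pp$absorbance[perm, ], pp$meta$group[perm],
                  pp$meta$subject_id[perm], cv = FALSE)
  expect_equal(fit_p$ld1, fit$ld1[perm], tolerance = 1e-8)
  fit_s <- pcalda(7.3 * pp$absorbance, pp$meta$group, pp$meta$subject_id,
                  cv = FALSE)
  expect_equal(cor(fit_s$ld1, fit$ld1), 1, tolerance = 1e-8)
})

test_that("cluster vectors localise an implanted single-band effect", {
  ds <- tiny_two_class(n_per_group = 10, r = 2, effect_at = 1304,
                       delta = 0.08, seed = 6)
  pp <- apply_recipe(average_replicates(ds), preprocess_recipe("rubberband"))
  fit <- pcalda(pp, n_pcs = 5, cv = FALSE)
  cvset <- cluster_vectors(fit, wavenumbers = pp$wavenumbers)
  expect_length(cvset$discriminant_track, length(pp$wavenumbers))
  expect_equal(nrow(cvset$pseudo_spectra), 2)
  peak_wn <- pp$wavenumbers[which.max(cvset$discriminant_track)]
  expect_lte(abs(peak_wn - 1304), 4)
  # two identical classes: no dominant structure in the track
  ds0 <- tiny_two_class(n_per_group = 10, r = 2, effect_at = NULL, seed = 8)
  pp0 <- apply_recipe(average_replicates(ds0), preprocess_recipe("rubberband"))
  cv0 <- cluster_vectors(pcalda(pp0, n_pcs = 5, cv = FALSE),
                         wavenumbers = pp0$wavenumbers)
  expect_lt(max(cv0$discriminant_track),
            5 * median(cv0$discriminant_track) +
              max(cvset$discriminant_track) * 0.5)
})

test_that("pcalda methods print, predict and expose coefficients", {
  ds <- tiny_two_class(n_per_group = 4, r = 2, seed = 13)
  pp <- apply_recipe(ds, preprocess_recipe("rubberband"))
  fit <- pcalda(pp, n_pcs = 3)
  expect_output(print(fit), "pcalda")
  expect_output(print(summary(fit)), "PCA-LDA")
  expect_length(coef(fit), 3)
  cls <- predict(fit, pp, type = "class")
  expect_gte(mean(cls == pp$meta$group), 0.8)
  expect_length(predict(fit, pp$absorbance[1:2, , drop = FALSE]), 2)
})
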