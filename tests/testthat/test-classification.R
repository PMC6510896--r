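test_that("Kennard-Stone starts from the most distant pair and partitions subjects", {
  # 3 collinear points plus a far outlier: first two selections are the
  # maximally distant pair
  x <- matrix(c(0, 1, 2, 50), ncol = 1)
  expect_equal(sort(ftirstrat:::kennard_stone_order(x)[1:2]), c(1, 4))

  ds <- tiny_two_class(n_per_group = 6, r = 2)
  avg <- average_replicates(apply_recipe(ds, preprocess_recipe("rubberband")))
  plan <- kennard_stone_split(avg)
  expect_length(intersect(plan$train_subjects, plan$test_subjects), 0)
  expect_setequal(c(plan$train_subjects, plan$test_subjects),
                  unique(ds$meta$subject_id))
  # split is per class: round(2/3 * 6) = 4 train subjects per class
  for (grp in c("HC", "CVID")) {
    ids <- unique(ds$meta$subject_id[ds$meta$group == grp])
    expect_length(intersect(plan$train_subjects, ids), 4)
  }
  expect_error(kennard_stone_split(avg, fraction = 1.2), "fraction")
  # replicate-level input is refused (split is defined on subject means)
  expect_error(kennard_stone_split(ds), "one.*spectrum per subject")
})

test_that("Kennard-Stone equals the brute-force max-min oracle", {
  set.seed(14)
  for (rep_i in 1:5) {
    x <- matrix(rnorm(20 * 6), 20, 6)
    expect_identical(ftirstrat:::kennard_stone_order(x), oracle_kennard_stone(x))
  }
})

test_that("grid search returns a grid member, aces separable data, and is order-invariant", {
  set.seed(15)
  n <- 12
  x <- rbind(matrix(rnorm(n * 4, 0, 0.3), n), matrix(rnorm(n * 4, 3, 0.3), n))
  lab <- rep(c("HC", "CVID"), each = n)
  subj <- rep(sprintf("s%02d", 1:8), each = 3)
  cfg <- svm_config(c_grid = c(1, 4, 16), gamma_grid = c(0.01, 0.1, 1),
                    folds = 4, seed = 2)
  gs <- svm_grid_search(x, lab, subj, cfg)
  expect_true(gs$cost %in% cfg$c_grid && gs$gamma %in% cfg$gamma_grid)
  expect_equal(gs$cv_accuracy, 1.0)
  # reordering the grids does not change the argmax (sorted + tie-break)
  cfg2 <- svm_config(c_grid = c(16, 1, 4), gamma_grid = c(1, 0.01, 0.1),
                     folds = 4, seed = 2)
  gs2 <- svm_grid_search(x, lab, subj, cfg2)
  expect_equal(gs2[c("cost", "gamma")], gs[c("cost", "gamma")])
  expect_error(svm_config(c_grid = numeric(0)), "empty")
  expect_error(svm_config(folds = 1), "folds")
})

test_that("grid-search folds never split a subject", {
  lab <- rep(c("HC", "CVID"), each = 12)
  subj <- rep(sprintf("s%02d", 1:8), each = 3)
  fold <- ftirstrat:::subject_folds(subj, lab, k = 3, seed = 5)
  per_subject <- tapply(fold, subj, function(f) length(unique(f)))
  expect_true(all(per_subject == 1))
  # stratification: each class's subjects spread over the folds
  subj_fold <- fold[!duplicated(subj)]
  subj_class <- lab[!duplicated(subj)]
  for (cl in c("HC", "CVID"))
    expect_gte(length(unique(subj_fold[subj_class == cl])), 2)
})

test_that("confusion reports compute accumulated-hit sensitivity and specificity", {
  # constructed counts: TP = 97, FN = 3 (CVID); TN = 93, FP = 7 (HC)
  truth <- c(rep("CVID", 100), rep("HC", 100))
  pred <- c(rep("CVID", 97), rep("HC", 3), rep("HC", 93), rep("CVID", 7))
  cr <- confusion_report(truth, pred, positive_class = "CVID")
  expect_equal(unname(cr$sensitivity["CVID"]), 97)
  expect_equal(unname(cr$specificity["CVID"]), 93)
  expect_equal(unname(rowSums(cr$counts)), c(100, 100))
  # all-correct: every per-class rate 100%
  cr2 <- confusion_report(truth, truth)
  expect_equal(unname(cr2$per_class_rate), c(100, 100))
  # absent true class: NA with a flag, not zero
  cr3 <- confusion_report(rep("HC", 5), c(rep("HC", 4), "CVID"),
                          classes = c("HC", "CVID"))
  expect_true(is.na(cr3$sensitivity["CVID"]))
  expect_identical(attr(cr3, "undefined_classes"), "CVID")
})

test_that("train/test subject overlap is rejected as leakage", {
  ds <- tiny_two_class(n_per_group = 3, r = 2)
  expect_error(
    svm_train_predict(ds, ds, cost = 1),
    "leakage")
})

test_that("end-to-end classification is deterministic and leak-free", {
  sim <- simulate_spectra(sim_config(n_hc = 8, n_cvid_non = 3,
                                     n_cvid_comp = 5, seed = 31,
                                     axis = seq(900, 1800, by = 4)))
  cfg <- svm_config(c_grid = c(1, 16), gamma_grid = c(0.1, 1),
                    folds = 3, seed = 31)
  r1 <- run_classification(sim$dataset, cfg = cfg)
  r2 <- run_classification(sim$dataset, cfg = cfg)
  expect_identical(r1$confusion$counts, r2$confusion$counts)
  expect_identical(r1[c("cost", "gamma", "cv_accuracy")],
                   r2[c("cost", "gamma", "cv_accuracy")])
  expect_length(intersect(r1$split$train_subjects, r1$split$test_subjects), 0)
  rates <- unlist(r1$confusion$per_class_rate)
  expect_true(all(rates >= 0 & rates <= 100, na.rm = TRUE))
})

test_that("test accuracy increases with implanted effect amplitude", {
  acc <- sapply(c(0, 0.5, 1), function(mult) {
    eff <- default_effects()
    eff$delta <- eff$delta * mult
    sim <- simulate_spectra(sim_config(n_hc = 10, n_cvid_non = 3,
                                       n_cvid_comp = 7, seed = 77,
                                       effects = eff,
                                       axis = seq(900, 1800, by = 4)))
    r <- run_classification(sim$dataset,
                            cfg = svm_config(c_grid = 4, gamma_grid = 0.5,
                                             folds = 3, seed = 77))
    mean(r$confusion$predictions == r$confusion$truth)
  })
  # non-decreasing up to sampling error
  expect_gte(acc[3], acc[1] - 0.05)
  expect_gte(acc[3], acc[2] - 0.05)
  expect_gte(acc[3], 0.9)
})
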