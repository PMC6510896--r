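#' Kennard-Stone patient-level train/test split
#'
#' Splits the subjects of each class into training and test sets with the
#' Kennard-Stone algorithm, applied to subject-mean preprocessed spectra:
#' within a class, the two mutually most distant subjects (Euclidean
#' distance) seed the training set, then subjects are added one at a time
#' by the max-min rule — each step picks the subject whose smallest
#' distance to the already-selected training subjects is largest — until
#' `round(fraction * n_class)` are chosen. The remainder form the test
#' set. The procedure is deterministic and guarantees that all spectra of
#' one subject fall on the same side of the split.
#'
#' @param ds A subject-averaged, preprocessed [spectral_dataset()] (one
#'   spectrum per subject), or a numeric matrix.
#' @param labels Class label per row (from metadata `group` if omitted).
#' @param subjects Subject id per row (from metadata if omitted).
#' @param fraction Target training share per class, in (0, 1). Default 2/3.
#' @return An object of class `split_plan`: list with `train_subjects`,
#'   `test_subjects`, `fraction` and the per-class selection order.
#' @export
kennard_stone_split <- function(ds, labels = NULL, subjects = NULL,
                                fraction = 2 / 3) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  if (inherits(ds, "spectral_dataset")) {
    if (is.null(labels)) labels <- ds$meta$group
    if (is.null(subjects)) subjects <- ds$meta$subject_id
  }
  x <- as_matrix(ds)
  subjects <- as.character(subjects)
  if (anyDuplicated(subjects))
    stop("kennard_stone_split expects one (subject-averaged) spectrum per subject",
         call. = FALSE)
  labels <- as.character(labels)
  train <- character(0); order_by_class <- list()
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    if (length(rows) < 2)
      stop("class ", cl, " has fewer than 2 subjects", call. = FALSE)
    sel <- kennard_stone_order(x[rows, , drop = FALSE])
    n_train <- max(2L, round(fraction * length(rows)))
    n_train <- min(n_train, length(rows) - 1L)  # keep at least one test subject
    picked <- subjects[rows][sel[seq_len(n_train)]]
    train <- c(train, picked)
    order_by_class[[cl]] <- subjects[rows][sel]
  }
  structure(list(train_subjects = sort(train),
                 test_subjects = sort(setdiff(subjects, train)),
                 fraction = fraction,
                 selection_order = order_by_class),
            class = "split_plan")
}

# Full Kennard-Stone selection order over the rows of x: start with the
# two mutually most distant points, then repeatedly add the point whose
# minimum distance to the selected set is maximal. Ties break toward the
# lower row index.
kennard_stone_order <- function(x) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  first_pair <- which(d == max(d), arr.ind = TRUE)[1, ]
  sel <- sort(as.integer(first_pair))
  remaining <- setdiff(seq_len(n), sel)
  while (length(remaining)) {
    min_d <- apply(d[remaining, sel, drop = FALSE], 1, min)
    nxt <- remaining[which.max(min_d)]
    sel <- c(sel, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  sel
}

#' @export
print.split_plan <- function(x, ...) {
  cat("split_plan: ", length(x$train_subjects), " train / ",
      length(x$test_subjects), " test subjects (target fraction ",
      signif(x$fraction, 3), ")\n", sep = "")
  invisible(x)
}

#' SVM configuration
#'
#' Radial-basis-kernel SVM tuning setup: the (cost, gamma) grids searched,
#' the number of cross-validation folds used to score each grid point, and
#' the seed controlling fold assignment. Defaults follow the usual
#' libsvm-style coarse search: cost over powers of four from 2^-5 to 2^15
#' and gamma from 2^-15 to 2^3.
#'
#' @param c_grid Positive cost values.
#' @param gamma_grid Positive kernel widths.
#' @param folds Cross-validation folds (>= 2).
#' @param seed Integer seed for fold assignment.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(c_grid = 2^seq(-5, 15, by = 2),
                       gamma_grid = 2^seq(-15, 3, by = 2),
                       folds = 10, seed = 1L) {
  if (!length(c_grid) || !length(gamma_grid))
    stop("empty tuning grid", call. = FALSE)
  if (any(c_grid <= 0) || any(gamma_grid <= 0))
    stop("cost and gamma must be positive", call. = FALSE)
  if (folds < 2) stop("folds must be at least 2", call. = FALSE)
  structure(list(c_grid = sort(unique(c_grid)),
                 gamma_grid = sort(unique(gamma_grid)),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "svm_config")
}

# Subject-grouped stratified fold assignment: subjects of each class are
# shuffled (seeded) and dealt round-robin into folds, so every spectrum of
# a subject shares a fold and classes balance across folds.
subject_folds <- function(subjects, labels, k, seed) {
  subj <- unique(subjects)
  subj_class <- labels[match(subj, subjects)]
  fold_of <- integer(length(subj))
  names(fold_of) <- subj
  rng <- local_seed(seed)
  on.exit(restore_seed(rng))
  for (cl in unique(subj_class)) {
    s <- subj[subj_class == cl]
    s <- sample(s)
    fold_of[s] <- rep_len(seq_len(k), length(s))
  }
  fold_of[subjects]
}

#' Grid search for SVM tuning parameters
#'
#' Scores every (cost, gamma) pair of the configured grids by
#' subject-grouped, class-stratified k-fold cross-validation accuracy on
#' the training spectra, and returns the grid argmax. Grouping by subject
#' keeps replicate spectra of one subject inside a single fold, so the
#' fold accuracy is free of replicate leakage. Ties are broken toward the
#' smallest cost, then the smallest gamma (the smoother model), making the
#' result independent of grid ordering.
#'
#' @param x Training spectra (matrix or [spectral_dataset()]).
#' @param labels Class per spectrum.
#' @param subjects Subject id per spectrum.
#' @param cfg An [svm_config()].
#' @return List with `cost`, `gamma`, `cv_accuracy` and the full
#'   `accuracy_grid` matrix (rows = cost, columns = gamma).
#' @export
svm_grid_search <- function(x, labels = NULL, subjects = NULL, cfg = svm_config()) {
  if (inherits(x, "spectral_dataset")) {
    if (is.null(labels)) labels <- x$meta$group
    if (is.null(subjects)) subjects <- x$meta$subject_id
  }
  xm <- as_matrix(x)
  labels <- factor(labels)
  subjects <- as.character(subjects)
  k <- cfg$folds
  if (any(table(labels[!duplicated(subjects)]) < k))
    warning("a class has fewer subjects than folds; folds will be uneven")
  fold <- subject_folds(subjects, as.character(labels), k, cfg$seed)
  acc <- matrix(NA_real_, length(cfg$c_grid), length(cfg$gamma_grid),
                dimnames = list(cost = format(cfg$c_grid, trim = TRUE),
                                gamma = format(cfg$gamma_grid, trim = TRUE)))
  for (ci in seq_along(cfg$c_grid)) {
    for (gi in seq_along(cfg$gamma_grid)) {
      hits <- 0L; total <- 0L
      for (f in seq_len(k)) {
        te <- fold == f
        if (!any(te) || length(unique(labels[!te])) < 2) next
        fit <- e1071::svm(xm[!te, , drop = FALSE], labels[!te],
                          kernel = "radial", cost = cfg$c_grid[ci],
                          gamma = cfg$gamma_grid[gi], scale = FALSE)
        pred <- stats::predict(fit, xm[te, , drop = FALSE])
        hits <- hits + sum(pred == labels[te])
        total <- total + sum(te)
      }
      acc[ci, gi] <- hits / total
    }
  }
  best <- which(acc == max(acc), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(cost = cfg$c_grid[best[1]], gamma = cfg$gamma_grid[best[2]],
       cv_accuracy = max(acc), accuracy_grid = acc)
}

#' Train an SVM and evaluate it on held-out spectra
#'
#' Fits a radial-kernel SVM on the training spectra and predicts every
#' test spectrum, assembling a spectrum-level confusion report from the
#' accumulated hits (true/false positives and negatives pooled over all
#' test spectra). Training and test sets must be subject-disjoint.
#'
#' @param train,test Matrices or [spectral_dataset()]s.
#' @param train_labels,test_labels Class per spectrum (metadata `group`
#'   when datasets are given).
#' @param train_subjects,test_subjects Subject ids (leakage check).
#' @param cost,gamma SVM parameters, e.g. from [svm_grid_search()].
#' @param positive_class Class treated as "positive" for the headline
#'   sensitivity/specificity (default `"CVID"`, the disease class). With
#'   more than two classes each class is scored one-vs-rest.
#' @return An object of class `confusion_report`: `counts` (true x
#'   predicted), `per_class_rate` (% of each true class correctly
#'   assigned), `sensitivity` and `specificity` per class (%), and the
#'   predictions. Rates for a class absent from the test set are `NA`
#'   with an `undefined_classes` attribute naming them.
#' @export
svm_train_predict <- function(train, test, train_labels = NULL,
                              test_labels = NULL, train_subjects = NULL,
                              test_subjects = NULL, cost = 1, gamma = NULL,
                              positive_class = "CVID") {
  if (inherits(train, "spectral_dataset")) {
    if (is.null(train_labels)) train_labels <- train$meta$group
    if (is.null(train_subjects)) train_subjects <- train$meta$subject_id
  }
  if (inherits(test, "spectral_dataset")) {
    if (is.null(test_labels)) test_labels <- test$meta$group
    if (is.null(test_subjects)) test_subjects <- test$meta$subject_id
  }
  xtr <- as_matrix(train); xte <- as_matrix(test)
  if (!is.null(train_subjects) && !is.null(test_subjects) &&
      length(common <- intersect(train_subjects, test_subjects)))
    stop("subject leakage between train and test: ",
         paste(utils::head(common, 5), collapse = ", "), call. = FALSE)
  if (is.null(gamma)) gamma <- 1 / ncol(xtr)
  lv <- unique(c(train_labels, test_labels))
  fit <- e1071::svm(xtr, factor(train_labels, levels = lv),
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  pred <- as.character(stats::predict(fit, xte))
  confusion_report(test_labels, pred, classes = lv,
                   positive_class = positive_class)
}

#' Build a confusion report from true and predicted labels
#'
#' @param truth,pred Character vectors of true and predicted classes.
#' @param classes Class order for the tables (default: order of first
#'   appearance in `truth` then `pred`).
#' @param positive_class See [svm_train_predict()].
#' @return A `confusion_report`.
#' @export
confusion_report <- function(truth, pred, classes = unique(c(truth, pred)),
                             positive_class = classes[1]) {
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  counts <- table(true = truth, predicted = pred)
  totals <- rowSums(counts)
  per_class_rate <- ifelse(totals > 0, 100 * diag(counts) / totals, NA_real_)
  sens <- spec <- setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    tp <- counts[cl, cl]
    fn <- totals[cl] - tp
    fp <- sum(counts[, cl]) - tp
    tn <- sum(counts) - tp - fn - fp
    sens[cl] <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    spec[cl] <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  }
  undef <- classes[totals == 0]
  structure(list(counts = counts, per_class_rate = per_class_rate,
                 sensitivity = sens, specificity = spec,
                 positive_class = positive_class,
                 predictions = as.character(pred),
                 truth = as.character(truth)),
            class = "confusion_report",
            undefined_classes = undef)
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("confusion_report (", sum(x$counts), " spectra)\n", sep = "")
  print(x$counts)
  cat("per-class correct (%):",
      paste(sprintf("%s=%.1f", names(x$per_class_rate), x$per_class_rate),
            collapse = "  "), "\n")
  pc <- x$positive_class
  if (pc %in% names(x$sensitivity))
    cat(sprintf("sensitivity (%s) = %.1f%%, specificity = %.1f%%\n",
                pc, x$sensitivity[pc], x$specificity[pc]))
  u <- attr(x, "undefined_classes")
  if (length(u)) cat("undefined for absent class(es):",
                     paste(u, collapse = ", "), "\n")
  invisible(x)
}

#' End-to-end SVM classification of a spectral dataset
#'
#' Composes the full classification pipeline: preprocess, extract the
#' spectral region, Kennard-Stone split at subject level (on
#' subject-averaged spectra), grid-search the SVM tuning parameters by
#' subject-grouped cross-validation on the training spectra, then train on
#' all training spectra and score the held-out test spectra.
#'
#' @param ds A raw [spectral_dataset()] (one biofluid).
#' @param recipe A [preprocess_recipe()]; default the Savitzky-Golay
#'   second-derivative variant used for classification.
#' @param region `"fingerprint"`, `"high"` or numeric bounds.
#' @param labelling `"two_class"` (HC vs CVID) or `"three_class"`.
#' @param cfg An [svm_config()].
#' @param fraction Training share for the Kennard-Stone split.
#' @param spectra_level Train/test on individual replicate spectra
#'   (`TRUE`, default) or on subject-averaged spectra.
#' @return An object of class `classification_result`: the `split_plan`,
#'   chosen `cost`/`gamma`/`cv_accuracy`, the test-set
#'   `confusion_report`, and provenance (`seed`, `region`, `labelling`).
#' @export
run_classification <- function(ds, recipe = preprocess_recipe("sg2d"),
                               region = "fingerprint",
                               labelling = c("two_class", "three_class"),
                               cfg = svm_config(), fraction = 2 / 3,
                               spectra_level = TRUE) {
  labelling <- match.arg(labelling)
  avg <- average_replicates(ds)
  pp_avg <- select_region(apply_recipe(avg, recipe), region)
  plan <- kennard_stone_split(pp_avg,
                              labels = class_labels(pp_avg, labelling),
                              fraction = fraction)
  work <- if (spectra_level) select_region(apply_recipe(ds, recipe), region)
          else pp_avg
  in_train <- work$meta$subject_id %in% plan$train_subjects
  tr <- subset_spectra(work, in_train)
  te <- subset_spectra(work, !in_train)
  lab_tr <- class_labels(tr, labelling)
  lab_te <- class_labels(te, labelling)
  gs <- svm_grid_search(tr, labels = lab_tr, subjects = tr$meta$subject_id,
                        cfg = cfg)
  rep <- svm_train_predict(tr, te, train_labels = lab_tr,
                           test_labels = lab_te,
                           train_subjects = tr$meta$subject_id,
                           test_subjects = te$meta$subject_id,
                           cost = gs$cost, gamma = gs$gamma)
  structure(list(split = plan, cost = gs$cost, gamma = gs$gamma,
                 cv_accuracy = gs$cv_accuracy, confusion = rep,
                 region = region, labelling = labelling,
                 seed = cfg$seed, folds = cfg$folds),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("classification_result: region=", if (is.character(x$region)) x$region
      else paste(x$region, collapse = "-"),
      ", labelling=", x$labelling,
      sprintf(", SVM cost=%g gamma=%g (CV acc %.1f%%)\n",
              x$cost, x$gamma, 100 * x$cv_accuracy), sep = "")
  print(x$confusion)
  invisible(x)
}
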