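#' Principal component analysis of spectra
#'
#' Centred singular-value decomposition of a spectral matrix. Components
#' are ordered by explained variance and carry a deterministic sign
#' convention: the largest-magnitude element of each loading vector is
#' made positive, so repeated fits (and fits by other SVD routines) agree
#' exactly rather than up to sign.
#'
#' @param x Numeric matrix (spectra in rows) or a [spectral_dataset()].
#' @param n_pcs Number of components to retain, or a fraction in (0, 1)
#'   interpreted as a variance target (smallest count whose cumulative
#'   explained fraction reaches it). Default keeps `min(n - 1, p)`.
#' @return An object of class `spectral_pca`: list with `mean` (the mean
#'   spectrum), `loadings` (`n_pcs` x p, orthonormal rows), `scores`
#'   (n x `n_pcs`) and `explained` (per-PC fraction of total variance).
#' @export
pca_fit <- function(x, n_pcs = NULL) {
  x <- as_matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  rank_max <- min(n - 1L, p)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc, nu = rank_max, nv = rank_max)
  var_all <- sv$d^2
  explained_all <- var_all / sum(var_all)
  if (is.null(n_pcs)) {
    k <- rank_max
  } else if (length(n_pcs) == 1 && n_pcs > 0 && n_pcs < 1) {
    k <- which(cumsum(explained_all) >= n_pcs - 1e-12)[1]
    if (is.na(k)) k <- rank_max
  } else {
    k <- as.integer(n_pcs)
    if (k < 1 || k > rank_max)
      stop("n_pcs must be between 1 and ", rank_max, call. = FALSE)
  }
  load <- t(sv$v[, seq_len(k), drop = FALSE])     # k x p
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  # sign convention: largest |loading| element positive per component
  for (j in seq_len(k)) {
    i_max <- which.max(abs(load[j, ]))
    if (load[j, i_max] < 0) {
      load[j, ] <- -load[j, ]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(mean = mu, loadings = load, scores = scores,
                 explained = explained_all[seq_len(k)]),
            class = "spectral_pca")
}

as_matrix <- function(x) {
  if (inherits(x, "spectral_dataset")) x$absorbance else as.matrix(x)
}

#' Project new spectra onto a fitted PCA
#'
#' @param object A `spectral_pca`.
#' @param newdata Matrix or [spectral_dataset()] on the same axis.
#' @param ... Unused.
#' @return Score matrix (rows = spectra, columns = PCs).
#' @export
predict.spectral_pca <- function(object, newdata, ...) {
  sweep(as_matrix(newdata), 2, object$mean) %*% t(object$loadings)
}

#' @export
print.spectral_pca <- function(x, ...) {
  cat("spectral_pca:", nrow(x$scores), "samples,", nrow(x$loadings),
      "components;", sprintf("%.1f%%", 100 * sum(x$explained)),
      "variance retained\n")
  invisible(x)
}

#' PCA-LDA of spectra
#'
#' Fits the discriminant model used throughout biofluid spectrochemistry:
#' a principal component decomposition of the (preprocessed) spectra
#' followed by Fisher linear discriminant analysis on the retained PC
#' scores. The first discriminant axis (LD1) maximises between-class over
#' pooled within-class variance of the scores; each sample's LD1 score is
#' the quantity plotted in 1D "scores plots". Cross-validated scores are
#' computed leave-one-subject-out: for each subject, all of that subject's
#' spectra are removed, PCA and LDA are refitted from scratch on the
#' remainder, and the held-out spectra are projected through the refitted
#' model, so replicate spectra of one subject can never inform their own
#' score. A Welch two-tailed t-test on the cross-validated LD1 scores of
#' the first two classes summarises class separation.
#'
#' @param x Numeric matrix (spectra in rows) or a preprocessed
#'   [spectral_dataset()].
#' @param labels Class label per spectrum. Taken from the dataset metadata
#'   (`group`) when `x` is a dataset and `labels` is `NULL`.
#' @param subjects Subject identifier per spectrum (defines the
#'   cross-validation unit). Taken from metadata when available.
#' @param n_pcs PC count, a variance-target fraction in (0, 1), or `NULL`
#'   for the default: the smallest count explaining at least 99% of
#'   variance, capped at (number of subjects - 2).
#' @param cv Compute leave-one-subject-out cross-validated LD1 scores?
#' @param ridge Ridge added to the pooled within-class covariance,
#'   relative to its trace, to keep the Fisher direction defined in
#'   singular cases.
#' @return An object of class `pcalda` with components `pca`
#'   (`spectral_pca`), `weights` (LD1 direction over retained PCs),
#'   `ld1` (per-sample LD1 score), `class_means_ld1`, `cv_ld1`
#'   (when `cv = TRUE`), `cv_p_value`, `labels`, `subjects`, `classes`
#'   and `n_pcs`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60), 10), matrix(rnorm(60, mean = 1), 10))
#' lab <- rep(c("HC", "CVID"), each = 10)
#' fit <- pcalda(x, lab, subjects = paste0("s", 1:20), n_pcs = 3)
#' summary(fit)
pcalda <- function(x, labels = NULL, subjects = NULL, n_pcs = NULL,
                   cv = TRUE, ridge = 1e-8) {
  if (inherits(x, "spectral_dataset")) {
    if (is.null(labels)) labels <- x$meta$group
    if (is.null(subjects)) subjects <- x$meta$subject_id
  }
  xm <- as_matrix(x)
  if (is.null(labels)) stop("labels are required", call. = FALSE)
  labels <- as.character(labels)
  if (is.null(subjects)) subjects <- paste0("row", seq_len(nrow(xm)))
  subjects <- as.character(subjects)
  classes <- unique(labels)
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  subj_class <- tapply(labels, subjects, function(l) l[1])
  if (any(table(subj_class) < 2))
    stop("each class needs at least 2 subjects for subject-level CV",
         call. = FALSE)
  n_subjects <- length(unique(subjects))

  fit_once <- function(xtr, ltr, k_spec, n_subj_tr) {
    k_cap <- max(1L, n_subj_tr - 2L)
    pca <- if (is.null(k_spec)) {
      p0 <- pca_fit(xtr, n_pcs = 0.99)
      k <- min(nrow(p0$loadings), k_cap)
      if (k < nrow(p0$loadings)) pca_fit(xtr, n_pcs = k) else p0
    } else pca_fit(xtr, n_pcs = k_spec)
    w <- fisher_ld1(pca$scores, ltr, ridge = ridge)
    list(pca = pca, w = w)
  }

  full <- fit_once(xm, labels, n_pcs, n_subjects)
  ld1 <- as.numeric(full$pca$scores %*% full$w)
  class_means <- tapply(ld1, labels, mean)[classes]

  cv_ld1 <- NULL; cv_p <- NA_real_
  if (cv) {
    cv_ld1 <- numeric(nrow(xm))
    for (s in unique(subjects)) {
      hold <- subjects == s
      f <- fit_once(xm[!hold, , drop = FALSE], labels[!hold], n_pcs,
                    length(unique(subjects[!hold])))
      sc <- predict.spectral_pca(f$pca, xm[hold, , drop = FALSE])
      cv_ld1[hold] <- as.numeric(sc %*% f$w)
    }
    a <- cv_ld1[labels == classes[1]]
    b <- cv_ld1[labels == classes[2]]
    cv_p <- stats::t.test(a, b)$p.value
  }

  structure(list(pca = full$pca, weights = full$w, ld1 = ld1,
                 class_means_ld1 = class_means, cv_ld1 = cv_ld1,
                 cv_p_value = cv_p, labels = labels, subjects = subjects,
                 classes = classes, n_pcs = nrow(full$pca$loadings),
                 ridge = ridge),
            class = "pcalda")
}

# Fisher LD1 direction on score space. Two classes: w = Sw^-1 (m1 - m2);
# more classes: leading eigenvector of Sw^-1 Sb. Pooled within-class
# covariance is regularised by ridge * trace / dim.
fisher_ld1 <- function(scores, labels, ridge = 1e-8) {
  classes <- unique(labels)
  k <- ncol(scores)
  sw <- matrix(0, k, k)
  for (cl in classes) {
    xc <- scores[labels == cl, , drop = FALSE]
    xc <- sweep(xc, 2, colMeans(xc))
    sw <- sw + crossprod(xc)
  }
  sw <- sw / (nrow(scores) - length(classes))
  sw <- sw + diag(ridge * sum(diag(sw)) / k + 1e-300, k)
  if (length(classes) == 2) {
    m1 <- colMeans(scores[labels == classes[1], , drop = FALSE])
    m2 <- colMeans(scores[labels == classes[2], , drop = FALSE])
    w <- solve(sw, m1 - m2)
  } else {
    gm <- colMeans(scores)
    sb <- matrix(0, k, k)
    for (cl in classes) {
      mc <- colMeans(scores[labels == cl, , drop = FALSE])
      nc <- sum(labels == cl)
      sb <- sb + nc * tcrossprod(mc - gm)
    }
    eg <- eigen(solve(sw, sb))
    w <- Re(eg$vectors[, 1])
  }
  w <- w / sqrt(sum(w^2))
  # deterministic orientation, independent of row order: the
  # lexicographically first class projects positive
  ref <- sort(classes)
  m1 <- colMeans(scores[labels == ref[1], , drop = FALSE])
  m2 <- colMeans(scores[labels == ref[2], , drop = FALSE])
  if (sum((m1 - m2) * w) < 0) w <- -w
  w
}

#' @export
print.pcalda <- function(x, ...) {
  cat("pcalda: ", length(x$classes), " classes (",
      paste(x$classes, collapse = ", "), "), ", x$n_pcs, " PCs, ",
      length(x$ld1), " spectra, ", length(unique(x$subjects)),
      " subjects\n", sep = "")
  if (!is.na(x$cv_p_value))
    cat("  leave-one-subject-out LD1 t-test p =",
        format.pval(x$cv_p_value, digits = 3), "\n")
  invisible(x)
}

#' @export
summary.pcalda <- function(object, ...) {
  res <- list(classes = object$classes, n_pcs = object$n_pcs,
              explained = sum(object$pca$explained),
              class_means_ld1 = object$class_means_ld1,
              cv_p_value = object$cv_p_value,
              n_subjects = length(unique(object$subjects)),
              n_spectra = length(object$ld1))
  class(res) <- "summary.pcalda"
  res
}

#' @export
print.summary.pcalda <- function(x, ...) {
  cat("PCA-LDA fit\n")
  cat("  spectra:", x$n_spectra, " subjects:", x$n_subjects, "\n")
  cat("  PCs retained:", x$n_pcs,
      sprintf("(%.1f%% variance)", 100 * x$explained), "\n")
  cat("  class mean LD1 scores:\n")
  print(round(x$class_means_ld1, 4))
  if (!is.na(x$cv_p_value))
    cat("  cross-validated LD1 separation p =",
        format.pval(x$cv_p_value, digits = 3), "\n")
  invisible(x)
}

#' @export
coef.pcalda <- function(object, ...) object$weights

#' Project new spectra through a fitted PCA-LDA model
#'
#' @param object A [pcalda()] fit.
#' @param newdata Matrix or [spectral_dataset()] on the model's axis.
#' @param type `"ld1"` for discriminant scores, `"class"` for hard
#'   assignment to the nearest class mean on LD1.
#' @param ... Unused.
#' @return Numeric LD1 scores or a character vector of class labels.
#' @export
predict.pcalda <- function(object, newdata,
                           type = c("ld1", "class"), ...) {
  type <- match.arg(type)
  sc <- predict.spectral_pca(object$pca, newdata)
  ld1 <- as.numeric(sc %*% object$weights)
  if (type == "ld1") return(ld1)
  cm <- object$class_means_ld1
  names(cm)[apply(abs(outer(ld1, cm, `-`)), 1, which.min)]
}

#' 1D discriminant scores plot
#'
#' Strip chart of (cross-validated, when available) LD1 scores by class —
#' the standard 1D scores-plot view of a PCA-LDA fit.
#'
#' @param x A [pcalda()] fit.
#' @param cv Plot cross-validated scores when available?
#' @param ... Passed to [graphics::stripchart()].
#' @export
plot.pcalda <- function(x, cv = TRUE, ...) {
  sc <- if (cv && !is.null(x$cv_ld1)) x$cv_ld1 else x$ld1
  graphics::stripchart(split(sc, x$labels), vertical = TRUE,
                       method = "jitter", pch = 1,
                       ylab = "LD1 score",
                       main = if (cv && !is.null(x$cv_ld1))
                         "Cross-validated PCA-LDA scores" else "PCA-LDA scores",
                       ...)
  invisible(x)
}

#' Cluster vectors of a PCA-LDA model
#'
#' Back-projects the LD1 direction through the PCA loadings into
#' wavenumber space. The absolute back-projection (the "discriminant
#' track") shows, per wavenumber, how strongly that wavenumber drives the
#' class separation; its peaks are candidate spectral biomarkers. Each
#' class additionally gets a pseudo-spectrum: the back-projection scaled
#' by the class-mean LD1 score.
#'
#' @param model A [pcalda()] fit.
#' @param wavenumbers Optional wavenumber axis to attach (length = number
#'   of spectral variables).
#' @return An object of class `cluster_vectors`: list with
#'   `discriminant_track` (absolute back-projected LD1 loading per
#'   wavenumber), `pseudo_spectra` (one row per class) and `wavenumbers`.
#' @export
cluster_vectors <- function(model, wavenumbers = NULL) {
  stopifnot(inherits(model, "pcalda"))
  bp <- as.numeric(model$weights %*% model$pca$loadings)
  ps <- outer(as.numeric(model$class_means_ld1), bp)
  rownames(ps) <- names(model$class_means_ld1)
  if (is.null(wavenumbers)) wavenumbers <- seq_along(bp)
  structure(list(discriminant_track = abs(bp), back_projection = bp,
                 pseudo_spectra = ps, wavenumbers = wavenumbers),
            class = "cluster_vectors")
}

#' @export
print.cluster_vectors <- function(x, ...) {
  i <- which.max(x$discriminant_track)
  cat("cluster_vectors:", length(x$discriminant_track), "wavenumbers;",
      nrow(x$pseudo_spectra), "classes; strongest at",
      x$wavenumbers[i], "cm-1\n")
  invisible(x)
}
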