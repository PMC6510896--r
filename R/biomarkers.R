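#' Per-wavenumber t-test feature track
#'
#' Runs a two-sample two-tailed Welch t-test at every wavenumber between
#' the two classes and returns -log10(p) as the feature score. Scores are
#' computed on subject-averaged spectra by default, so the test's sample
#' size is the number of subjects, not the number of replicate spectra
#' (which would overstate significance through pseudo-replication);
#' `subject_average = FALSE` gives the spectrum-level variant.
#'
#' @param ds A preprocessed [spectral_dataset()] (typically the training
#'   portion), or a numeric matrix with `labels` and optional `subjects`.
#' @param labels Class per row (metadata `group` when `ds` is a dataset).
#' @param subjects Subject id per row.
#' @param subject_average Average replicates within subject first?
#' @param pooled Use the pooled-variance (classical Student) test instead
#'   of Welch?
#' @return An object of class `feature_track` with `method = "ttest"`,
#'   the `wavenumbers`, non-negative `score` (-log10 p), the raw
#'   `p_value`s and the class mean difference per wavenumber
#'   (`mean_diff`, first class minus second).
#' @export
ttest_track <- function(ds, labels = NULL, subjects = NULL,
                        subject_average = TRUE, pooled = FALSE) {
  prep <- track_input(ds, labels, subjects, subject_average)
  classes <- unique(prep$labels)
  if (length(classes) != 2)
    stop("t-test track needs exactly 2 classes, got ",
         length(classes), call. = FALSE)
  a <- prep$x[prep$labels == classes[1], , drop = FALSE]
  b <- prep$x[prep$labels == classes[2], , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("each class needs at least 2 samples", call. = FALSE)
  w <- if (pooled) pooled_columns(a, b) else welch_columns(a, b)
  feature_track("ttest", prep$wavenumbers, -log10(pmax(w$p, 1e-300)),
                p_value = w$p, mean_diff = w$mean_diff,
                classes = classes)
}

pooled_columns <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums(sweep(a, 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(b, 2, mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  t_stat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df),
       mean_diff = ma - mb)
}

track_input <- function(ds, labels, subjects, subject_average) {
  if (inherits(ds, "spectral_dataset")) {
    if (subject_average) ds <- average_replicates(ds)
    list(x = ds$absorbance, labels = labels %||% ds$meta$group,
         subjects = subjects %||% ds$meta$subject_id,
         wavenumbers = ds$wavenumbers)
  } else {
    x <- as.matrix(ds)
    if (subject_average && !is.null(subjects)) {
      idx <- split(seq_len(nrow(x)), subjects)
      idx <- idx[order(vapply(idx, `[`, integer(1), 1L))]
      x2 <- t(vapply(idx, function(i) colMeans(x[i, , drop = FALSE]),
                     numeric(ncol(x))))
      lab2 <- vapply(idx, function(i) as.character(labels[i[1]]), character(1))
      list(x = x2, labels = lab2, subjects = names(idx),
           wavenumbers = as.numeric(colnames(x) %||% seq_len(ncol(x))))
    } else {
      list(x = x, labels = as.character(labels),
           subjects = as.character(subjects %||% seq_len(nrow(x))),
           wavenumbers = suppressWarnings(
             as.numeric(colnames(x) %||% seq_len(ncol(x)))))
    }
  }
}

feature_track <- function(method, wavenumbers, score, ...) {
  structure(c(list(method = method, wavenumbers = wavenumbers,
                   score = as.numeric(score)), list(...)),
            class = "feature_track")
}

#' @export
print.feature_track <- function(x, ...) {
  i <- which.max(x$score)
  cat("feature_track [", x$method, "]: ", length(x$score),
      " wavenumbers; top score ", signif(x$score[i], 4), " at ",
      x$wavenumbers[i], " cm-1\n", sep = "")
  invisible(x)
}

#' Cluster-vector feature track
#'
#' Convenience wrapper: fits (or reuses) a PCA-LDA model on the
#' subject-averaged spectra and returns the absolute back-projected LD1
#' loading per wavenumber (the discriminant track of
#' [cluster_vectors()]) as a feature score.
#'
#' @param ds A preprocessed [spectral_dataset()].
#' @param labels,subjects As in [ttest_track()].
#' @param model Optional pre-fitted [pcalda()] model on the same data.
#' @param n_pcs Passed to [pcalda()]. Defaults to 10 for the track:
#'   back-projection needs a compact score space, because LD1 weight on
#'   low-variance noise components back-projects into unstructured
#'   wavenumber noise that drowns the class-difference bands; ten
#'   dominant components is the usual biospectroscopy operating point.
#' @return A `feature_track` with `method = "cluster_vector"`.
#' @export
cluster_vector_track <- function(ds, labels = NULL, subjects = NULL,
                                 model = NULL, n_pcs = 10) {
  prep <- track_input(ds, labels, subjects, subject_average = TRUE)
  if (is.null(model)) {
    if (!is.null(n_pcs))
      n_pcs <- min(n_pcs, nrow(prep$x) - 1L, ncol(prep$x))
    model <- pcalda(prep$x, prep$labels, prep$subjects, n_pcs = n_pcs,
                    cv = FALSE)
  }
  cv <- cluster_vectors(model, wavenumbers = prep$wavenumbers)
  feature_track("cluster_vector", prep$wavenumbers, cv$discriminant_track,
                back_projection = cv$back_projection)
}

#' Forward feature selection track
#'
#' Bootstrap forward feature selection guided by the PCA loadings. The
#' candidate pool is the `n_candidates` wavenumbers with the largest
#' variance-weighted aggregate absolute PCA loading (sum over PCs of the
#' explained-variance fraction times |loading|). In each of `rounds`
#' subject-level stratified bootstrap resamples, a two-sample Welch
#' t-test p-value is computed for every candidate, and features are
#' admitted forward in order of increasing p-value, skipping any
#' candidate within `round_separation` of one already admitted (flanks
#' of a band carry the same information as its centre), until
#' `max_features` are selected. The score is the number of rounds in
#' which each wavenumber was selected — the height of an FFS selection
#' histogram.
#'
#' @param ds Preprocessed training spectra (dataset or matrix).
#' @param labels,subjects As in [ttest_track()].
#' @param pca Optional fitted [pca_fit()] model on the (subject-averaged)
#'   training data; fitted internally when omitted.
#' @param rounds Number of bootstrap resamples (default 100).
#' @param seed Seed for the resampling.
#' @param max_features Features retained per round (default 6).
#' @param n_candidates How far down the loading ranking to search.
#' @param round_separation Within-round minimum wavenumber separation
#'   between admitted features (cm^-1); default 20, about two band
#'   widths, so one band contributes one feature per round.
#' @return A `feature_track` with `method = "ffs"`, scores = selection
#'   counts in `[0, rounds]`.
#' @export
ffs_track <- function(ds, labels = NULL, subjects = NULL, pca = NULL,
                      rounds = 100, seed = 1L, max_features = 6,
                      n_candidates = 60, round_separation = 20) {
  if (rounds < 1) stop("rounds must be at least 1", call. = FALSE)
  prep <- track_input(ds, labels, subjects, subject_average = TRUE)
  x <- prep$x; lab <- prep$labels; wn <- prep$wavenumbers
  classes <- unique(lab)
  if (length(classes) != 2)
    stop("forward feature selection needs exactly 2 classes", call. = FALSE)
  if (is.null(pca)) pca <- pca_fit(x)
  rank_score <- colSums(abs(pca$loadings) * pca$explained)
  candidates <- sort(order(rank_score, decreasing = TRUE)[
    seq_len(min(n_candidates, length(rank_score)))])
  counts <- numeric(ncol(x))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  ia <- which(lab == classes[1]); ib <- which(lab == classes[2])
  for (r in seq_len(rounds)) {
    ra <- sample(ia, length(ia), replace = TRUE)
    rb <- sample(ib, length(ib), replace = TRUE)
    p <- welch_columns(x[ra, candidates, drop = FALSE],
                       x[rb, candidates, drop = FALSE])$p
    sel <- integer(0)
    for (cand in candidates[order(p)]) {
      if (!length(sel) || all(abs(wn[sel] - wn[cand]) > round_separation))
        sel <- c(sel, cand)
      if (length(sel) >= max_features) break
    }
    counts[sel] <- counts[sel] + 1
  }
  feature_track("ffs", wn, counts, rounds = rounds)
}

#' Detect the most segregating peaks of a feature track
#'
#' Finds local maxima of the score (strictly greater than both
#' neighbours; plateaus contribute their lowest-wavenumber point;
#' endpoints qualify when greater than their single neighbour), ranks
#' them by height, and greedily retains them in rank order while
#' discarding any candidate within `min_separation` of an
#' already-retained peak — nearby wavenumbers ride on the same band, so
#' they carry no independent information. At most `k` peaks are kept;
#' ties in height break toward the lower wavenumber.
#'
#' @param track A `feature_track`.
#' @param k Maximum number of peaks (default 6).
#' @param min_separation Proximity radius in cm^-1 (default 10): a
#'   candidate at distance <= `min_separation` from a retained peak is
#'   omitted.
#' @return An object of class `biomarker_panel`: data frame `peaks`
#'   (wavenumber, method, score, p_value and direction where available)
#'   and data frame `omitted` recording proximity-filtered candidates.
#' @export
detect_peaks <- function(track, k = 6, min_separation = 10) {
  stopifnot(inherits(track, "feature_track"))
  s <- track$score
  wn <- track$wavenumbers
  cand <- local_maxima(s)
  ord <- cand[order(-s[cand], wn[cand])]
  kept <- integer(0); omitted <- integer(0)
  for (i in ord) {
    if (length(kept) && any(abs(wn[kept] - wn[i]) <= min_separation)) {
      omitted <- c(omitted, i)
    } else if (length(kept) < k) {
      kept <- c(kept, i)
    }
  }
  peak_row <- function(idx) {
    data.frame(wavenumber = wn[idx], method = rep(track$method, length(idx)),
               score = s[idx],
               p_value = if (!is.null(track$p_value)) track$p_value[idx]
                         else rep(NA_real_, length(idx)),
               direction = peak_direction(track, idx),
               stringsAsFactors = FALSE)
  }
  structure(list(peaks = peak_row(kept),
                 omitted = if (length(omitted))
                   cbind(peak_row(omitted),
                         rule = "within 10 cm-1 of a retained peak")
                 else cbind(peak_row(integer(0)), rule = character(0)),
                 min_separation = min_separation),
            class = "biomarker_panel")
}

# Direction of change in the disease class, when the track knows the sign
# of the class difference (t-test tracks; first class minus second).
peak_direction <- function(track, idx) {
  if (is.null(track$mean_diff) || is.null(track$classes))
    return(rep(NA_character_, length(idx)))
  d <- track$mean_diff[idx]
  cvid_first <- grepl("^CVID", track$classes[1])
  up <- if (cvid_first) d > 0 else d < 0
  ifelse(up, "up_in_CVID", "down_in_CVID")
}

# Indices of local maxima: strictly above both neighbours, plateaus give
# their first (lowest-wavenumber) point, endpoints count against their
# single neighbour.
local_maxima <- function(s) {
  s[!is.finite(s)] <- -Inf
  n <- length(s)
  if (n == 1) return(1L)
  out <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1] == s[i]) j <- j + 1L  # plateau [i, j]
    left_ok <- i == 1L || s[i - 1] < s[i]
    right_ok <- j == n || s[j + 1] < s[i]
    if (left_ok && right_ok) out <- c(out, i)
    i <- j + 1L
  }
  out
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat("biomarker_panel: ", nrow(x$peaks), " peak(s)",
      if (nrow(x$omitted)) paste0(", ", nrow(x$omitted),
                                  " omitted by proximity"), "\n", sep = "")
  if (nrow(x$peaks)) print(x$peaks, row.names = FALSE)
  invisible(x)
}

#' Merge per-method biomarker panels
#'
#' Unions the peaks of several extraction methods on one axis. A
#' wavenumber reported by two or more methods is flagged as corroborated
#' (independent methods agreeing strengthens its utility as a biomarker)
#' and kept once with its best score. The same 10 cm^-1 proximity rule is
#' then applied across methods: of two merged peaks closer than
#' `min_separation`, only the higher-scoring one is retained and the
#' omission is recorded.
#'
#' @param panels List of `biomarker_panel`s from [detect_peaks()].
#' @param min_separation Cross-method proximity radius (cm^-1).
#' @return A `biomarker_panel` whose `peaks` carry `methods` (comma-joined
#'   contributors), `n_methods` and `corroborated` columns.
#' @export
merge_panels <- function(panels, min_separation = 10) {
  if (!length(panels))
    return(structure(list(peaks = data.frame(), omitted = data.frame(),
                          min_separation = min_separation),
                     class = "biomarker_panel"))
  stopifnot(all(vapply(panels, inherits, logical(1), "biomarker_panel")))
  all_peaks <- do.call(rbind, lapply(panels, `[[`, "peaks"))
  if (!nrow(all_peaks))
    return(structure(list(peaks = all_peaks, omitted = all_peaks,
                          min_separation = min_separation),
                     class = "biomarker_panel"))
  # collapse exact wavenumber matches across methods
  by_wn <- split(all_peaks, all_peaks$wavenumber)
  merged <- do.call(rbind, lapply(by_wn, function(g) {
    best <- g[which.max(g$score), , drop = FALSE]
    dir <- unique(stats::na.omit(g$direction))
    data.frame(wavenumber = best$wavenumber,
               methods = paste(sort(unique(g$method)), collapse = ","),
               n_methods = length(unique(g$method)),
               score = best$score,
               p_value = suppressWarnings(min(g$p_value, na.rm = TRUE)),
               direction = if (length(dir) == 1) dir else NA_character_,
               stringsAsFactors = FALSE)
  }))
  merged$p_value[!is.finite(merged$p_value)] <- NA_real_
  merged$corroborated <- merged$n_methods >= 2
  ord <- order(-merged$score, merged$wavenumber)
  kept <- integer(0); omitted <- integer(0)
  for (i in ord) {
    if (length(kept) &&
        any(abs(merged$wavenumber[kept] - merged$wavenumber[i]) <= min_separation))
      omitted <- c(omitted, i)
    else kept <- c(kept, i)
  }
  kept <- kept[order(merged$wavenumber[kept])]
  om <- merged[omitted, , drop = FALSE]
  if (nrow(om)) om$rule <- "within 10 cm-1 of a higher-scoring biomarker"
  structure(list(peaks = merged[kept, , drop = FALSE],
                 omitted = om, min_separation = min_separation),
            class = "biomarker_panel")
}

#' Subject-level band-intensity comparisons at biomarker wavenumbers
#'
#' For each biomarker wavenumber and each requested group contrast,
#' compares the subjects' mean preprocessed absorbance (the mean of each
#' subject's ~20 replicate spectra) between the groups with a two-tailed
#' Welch t-test and a 95% confidence interval on the difference. Intended
#' for rubber-band + vector-normalised data, where band intensities are
#' positively peaked and interpretable. Direction of change is reported
#' for the disease side of the contrast (second group minus first when
#' the first is HC).
#'
#' @param ds A variant-A preprocessed [spectral_dataset()] (replicate
#'   level; subjects are averaged internally).
#' @param wavenumbers Biomarker wavenumbers (must lie on the axis), or a
#'   `biomarker_panel`.
#' @param contrasts List of length-2 character vectors from
#'   `{"HC", "CVID", "CVID_non", "CVID_comp"}`. Default: the four
#'   contrasts HC-CVID, HC-CVID_non, HC-CVID_comp, CVID_non-CVID_comp.
#' @param conf_level Confidence level (default 0.95).
#' @return A data frame of class `group_comparison` with one row per
#'   (wavenumber, contrast): group means, difference, CI bounds, p-value
#'   and direction.
#' @export
subject_intensity_analysis <- function(ds, wavenumbers,
                                       contrasts = list(
                                         c("HC", "CVID"),
                                         c("HC", "CVID_non"),
                                         c("HC", "CVID_comp"),
                                         c("CVID_non", "CVID_comp")),
                                       conf_level = 0.95) {
  if (inherits(wavenumbers, "biomarker_panel"))
    wavenumbers <- wavenumbers$peaks$wavenumber
  avg <- average_replicates(ds)
  # snap to the nearest axis point (within half a spacing) so literature
  # band positions that fall between grid points can be queried
  spacing <- if (length(avg$wavenumbers) > 1)
    avg$wavenumbers[2] - avg$wavenumbers[1] else 0
  cols <- vapply(wavenumbers, function(w) {
    i <- which.min(abs(avg$wavenumbers - w))
    if (abs(avg$wavenumbers[i] - w) > spacing / 2 + 1e-9) NA_integer_ else i
  }, integer(1))
  if (anyNA(cols))
    stop("wavenumber(s) not on the dataset axis: ",
         paste(wavenumbers[is.na(cols)], collapse = ", "), call. = FALSE)
  lab3 <- class_labels(avg, "three_class")
  lab2 <- avg$meta$group
  member <- function(g) switch(g,
    HC = lab2 == "HC", CVID = lab2 == "CVID",
    CVID_non = lab3 == "CVID_non", CVID_comp = lab3 == "CVID_comp",
    stop("unknown group label: ", g, call. = FALSE))
  rows <- list()
  for (ci in seq_along(contrasts)) {
    ga <- contrasts[[ci]][1]; gb <- contrasts[[ci]][2]
    ia <- member(ga); ib <- member(gb)
    if (sum(ia) < 2 || sum(ib) < 2)
      stop("contrast ", ga, " vs ", gb, " has a group with < 2 subjects",
           call. = FALSE)
    for (wi in seq_along(cols)) {
      va <- avg$absorbance[ia, cols[wi]]
      vb <- avg$absorbance[ib, cols[wi]]
      tt <- stats::t.test(va, vb, conf.level = conf_level)
      disease_minus_ref <- mean(vb) - mean(va)
      rows[[length(rows) + 1]] <- data.frame(
        wavenumber = wavenumbers[wi], group_a = ga, group_b = gb,
        mean_a = mean(va), mean_b = mean(vb),
        diff = mean(va) - mean(vb),
        ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
        p_value = tt$p.value,
        n_a = sum(ia), n_b = sum(ib),
        direction = if (disease_minus_ref > 0) "up_in_CVID" else "down_in_CVID",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Minimum sample size for a two-sample t-test
#'
#' Smallest group sizes at which a two-tailed two-sample t-test detects
#' the difference between two normal populations with the requested
#' power, under the noncentral-t model with Welch-Satterthwaite degrees
#' of freedom. Group sizes may be constrained to a ratio (e.g. the 30:21
#' control-to-patient ratio of a study cohort); the returned `n` is
#' minimal, i.e. power falls below the target one subject earlier.
#'
#' @param mean_a,sd_a,mean_b,sd_b Group means and standard deviations
#'   (sds > 0, means unequal).
#' @param alpha Two-sided significance level (default 0.05).
#' @param power_target Required power (default 0.80).
#' @param ratio `n_a / n_b` (default 1 for equal groups).
#' @return An object of class `power_result`: `n_a`, `n_b`,
#'   `achieved_power`, `power_at_n_minus_1`, plus the inputs.
#' @export
#' @examples
#' power_min_n(0, 1, 1, 1)           # classic d = 1 two-sample design
#' power_min_n(10.48, 1.72, 7.86, 2.37, ratio = 30 / 21)
power_min_n <- function(mean_a, sd_a, mean_b, sd_b, alpha = 0.05,
                        power_target = 0.80, ratio = 1) {
  if (sd_a <= 0 || sd_b <= 0) stop("standard deviations must be positive",
                                   call. = FALSE)
  if (mean_a == mean_b)
    stop("means are equal: no finite sample size reaches the target power",
         call. = FALSE)
  power_at <- function(nb) {
    na <- max(2, round(ratio * nb))
    if (nb < 2) return(0)
    se2 <- sd_a^2 / na + sd_b^2 / nb
    ncp <- abs(mean_a - mean_b) / sqrt(se2)
    df <- se2^2 / ((sd_a^2 / na)^2 / (na - 1) + (sd_b^2 / nb)^2 / (nb - 1))
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tc, df, ncp = ncp)
  }
  nb <- 2
  while (power_at(nb) < power_target) {
    nb <- nb + 1
    if (nb > 1e6) stop("no attainable sample size below 1e6", call. = FALSE)
  }
  structure(list(n_a = max(2, round(ratio * nb)), n_b = nb,
                 achieved_power = power_at(nb),
                 power_at_n_minus_1 = power_at(nb - 1),
                 alpha = alpha, power_target = power_target,
                 ratio = ratio,
                 effect_inputs = c(mean_a = mean_a, sd_a = sd_a,
                                   mean_b = mean_b, sd_b = sd_b)),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(paste0("power_result: n_a = %d, n_b = %d ",
                     "(power %.3f at alpha %.2f; %.3f one subject fewer)\n"),
              x$n_a, x$n_b, x$achieved_power, x$alpha,
              x$power_at_n_minus_1))
  invisible(x)
}
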