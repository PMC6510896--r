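#' Spectral dataset container
#'
#' A `spectral_dataset` holds a set of ATR-FTIR spectra that share one
#' wavenumber axis, together with per-spectrum sample metadata. The axis is
#' always stored ascending; inputs supplied descending (the usual
#' spectroscopic display convention) are flipped on construction.
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1, uniformly
#'   spaced. May be ascending or descending; stored ascending.
#' @param absorbance Numeric matrix, one row per spectrum, `length(wavenumbers)`
#'   columns.
#' @param meta Data frame with one row per spectrum and columns
#'   `subject_id`, `group` (`"HC"` or `"CVID"`), `subgroup`
#'   (`"none_assigned"`, `"complication_free"` or `"complications"`),
#'   `biofluid` (`"serum"` or `"plasma"`), `spot` (1..2, or 0 for
#'   subject-averaged spectra) and `replicate` (1..10, or 0).
#'
#' @return An object of class `spectral_dataset`: a list with elements
#'   `wavenumbers`, `absorbance` and `meta`.
#' @export
#' @examples
#' wn <- seq(900, 1800, by = 4)
#' ds <- spectral_dataset(wn, matrix(rnorm(2 * length(wn)), 2),
#'                        data.frame(subject_id = c("s1", "s2"),
#'                                   group = c("HC", "CVID"),
#'                                   subgroup = c("none_assigned", "complications"),
#'                                   biofluid = "serum", spot = 1L, replicate = 1L))
#' ds
spectral_dataset <- function(wavenumbers, absorbance, meta) {
  wavenumbers <- as.numeric(wavenumbers)
  if (is.data.frame(absorbance)) absorbance <- as.matrix(absorbance)
  if (!is.matrix(absorbance)) absorbance <- matrix(absorbance, nrow = 1L)
  storage.mode(absorbance) <- "double"
  if (length(wavenumbers) >= 2 && wavenumbers[1] > wavenumbers[length(wavenumbers)]) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[, rev(seq_len(ncol(absorbance))), drop = FALSE]
  }
  meta <- normalize_meta(meta)
  ds <- structure(list(wavenumbers = wavenumbers,
                       absorbance = absorbance,
                       meta = meta),
                  class = "spectral_dataset")
  validate_dataset(ds)
  ds
}

ds_groups <- c("HC", "CVID")
ds_subgroups <- c("none_assigned", "complication_free", "complications")
ds_biofluids <- c("serum", "plasma")

normalize_meta <- function(meta) {
  need <- c("subject_id", "group", "subgroup", "biofluid", "spot", "replicate")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols))
    stop("metadata column(s) missing: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  meta <- as.data.frame(meta)[, need]
  meta$subject_id <- as.character(meta$subject_id)
  meta$group <- as.character(meta$group)
  meta$subgroup <- as.character(meta$subgroup)
  meta$biofluid <- as.character(meta$biofluid)
  meta$spot <- as.integer(meta$spot)
  meta$replicate <- as.integer(meta$replicate)
  rownames(meta) <- NULL
  meta
}

#' Validate a spectral dataset
#'
#' Checks the container invariants: uniform ascending axis, finite
#' absorbance, metadata categories drawn from the allowed enumerations,
#' CVID-only subgroups, and no duplicated
#' (subject, biofluid, spot, replicate) record.
#'
#' @param ds A [spectral_dataset()].
#' @param axis_rtol Relative tolerance on axis spacing uniformity.
#' @return `ds`, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_dataset <- function(ds, axis_rtol = 1e-6) {
  wn <- ds$wavenumbers
  if (length(wn) < 1) stop("empty wavenumber axis", call. = FALSE)
  if (ncol(ds$absorbance) != length(wn))
    stop("absorbance has ", ncol(ds$absorbance), " columns but axis has ",
         length(wn), " points", call. = FALSE)
  if (nrow(ds$absorbance) != nrow(ds$meta))
    stop("absorbance has ", nrow(ds$absorbance), " rows but metadata has ",
         nrow(ds$meta), call. = FALSE)
  if (length(wn) >= 2) {
    d <- diff(wn)
    if (any(d <= 0)) stop("wavenumber axis not strictly increasing", call. = FALSE)
    if (max(abs(d - d[1])) > axis_rtol * abs(d[1]))
      stop("non-uniform wavenumber axis (spacing varies beyond tolerance)",
           call. = FALSE)
  }
  if (!all(is.finite(ds$absorbance)))
    stop("absorbance contains non-finite values", call. = FALSE)
  m <- ds$meta
  if (nrow(m)) {
    bad <- function(col, allowed)
      if (!all(m[[col]] %in% allowed))
        stop("invalid ", col, " value(s): ",
             paste(unique(setdiff(m[[col]], allowed)), collapse = ", "),
             call. = FALSE)
    bad("group", ds_groups)
    bad("subgroup", ds_subgroups)
    bad("biofluid", ds_biofluids)
    if (any(m$group == "HC" & m$subgroup != "none_assigned"))
      stop("subgroup assigned to a non-CVID subject", call. = FALSE)
    key <- paste(m$subject_id, m$biofluid, m$spot, m$replicate, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (subject, biofluid, spot, replicate) record(s): ",
           paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = "; "),
           call. = FALSE)
  }
  invisible(ds)
}

#' @export
print.spectral_dataset <- function(x, ...) {
  wn <- x$wavenumbers
  cat("spectral_dataset: ", nrow(x$absorbance), " spectra, ",
      length(wn), " wavenumbers (", wn[1], "-", wn[length(wn)], " cm-1",
      if (length(wn) > 1) paste0(", step ", signif(wn[2] - wn[1], 6)),
      ")\n", sep = "")
  if (nrow(x$meta)) {
    cat("  subjects: ", length(unique(x$meta$subject_id)),
        " | groups: ", paste(sprintf("%s=%d", names(table(x$meta$group)),
                                     table(x$meta$group)), collapse = " "),
        " | biofluids: ", paste(unique(x$meta$biofluid), collapse = ","),
        "\n", sep = "")
  }
  invisible(x)
}

#' Subset a spectral dataset by spectrum index
#'
#' @param ds A [spectral_dataset()].
#' @param i Integer or logical index over spectra (rows).
#' @return A `spectral_dataset` with the selected spectra.
#' @export
subset_spectra <- function(ds, i) {
  structure(list(wavenumbers = ds$wavenumbers,
                 absorbance = ds$absorbance[i, , drop = FALSE],
                 meta = ds$meta[i, , drop = FALSE]),
            class = "spectral_dataset")
}

#' Average replicate spectra within subject
#'
#' Collapses the (typically 2 spots x 10 points = 20) replicate spectra of
#' each subject and biofluid to their arithmetic mean, giving one spectrum
#' per subject per biofluid. Averaged records carry the sentinel
#' `spot = replicate = 0`. Applying the function to an already-averaged
#' dataset is the identity.
#'
#' @param ds A [spectral_dataset()].
#' @return A `spectral_dataset` with one row per (subject, biofluid).
#' @export
average_replicates <- function(ds) {
  validate_dataset(ds)
  m <- ds$meta
  key <- paste(m$subject_id, m$biofluid, sep = "\r")
  idx <- split(seq_len(nrow(m)), key)
  first <- vapply(idx, `[`, integer(1), 1L)
  ord <- order(first)  # preserve first-appearance order
  idx <- idx[ord]
  first <- first[ord]
  avg <- t(vapply(idx, function(i) colMeans(ds$absorbance[i, , drop = FALSE]),
                  numeric(ncol(ds$absorbance))))
  meta <- m[first, , drop = FALSE]
  meta$spot <- 0L
  meta$replicate <- 0L
  rownames(meta) <- NULL
  structure(list(wavenumbers = ds$wavenumbers,
                 absorbance = avg, meta = meta),
            class = "spectral_dataset")
}

#' Extract a spectral region
#'
#' Returns the sub-dataset whose axis lies within a closed wavenumber
#' interval. The two named regions follow biospectroscopy convention:
#' `"fingerprint"` is 900-1800 cm^-1 and `"high"` is 2800-3700 cm^-1; both
#' endpoints are included.
#'
#' @param ds A [spectral_dataset()].
#' @param region `"fingerprint"`, `"high"`, or a numeric length-2 vector
#'   `c(low, high)` in cm^-1.
#' @return A `spectral_dataset` restricted to the interval.
#' @export
select_region <- function(ds, region = c("fingerprint", "high")) {
  if (is.character(region)) {
    region <- match.arg(region)
    bounds <- switch(region, fingerprint = c(900, 1800), high = c(2800, 3700))
  } else {
    bounds <- sort(as.numeric(region))
    if (length(bounds) != 2 || any(!is.finite(bounds)))
      stop("region must be a name or a numeric c(low, high)", call. = FALSE)
  }
  keep <- ds$wavenumbers >= bounds[1] & ds$wavenumbers <= bounds[2]
  if (!any(keep))
    stop("requested region [", bounds[1], ", ", bounds[2],
         "] does not intersect the axis", call. = FALSE)
  structure(list(wavenumbers = ds$wavenumbers[keep],
                 absorbance = ds$absorbance[, keep, drop = FALSE],
                 meta = ds$meta),
            class = "spectral_dataset")
}

#' Class labels for a dataset
#'
#' Derives the classification labelling from the metadata: `"two_class"`
#' gives HC vs CVID; `"three_class"` splits CVID by clinical subgroup into
#' `CVID_non` (complication-free) and `CVID_comp` (with complications).
#'
#' @param ds A [spectral_dataset()].
#' @param labelling `"two_class"` or `"three_class"`.
#' @return Character vector of per-spectrum labels.
#' @export
class_labels <- function(ds, labelling = c("two_class", "three_class")) {
  labelling <- match.arg(labelling)
  m <- ds$meta
  if (labelling == "two_class") return(m$group)
  ifelse(m$group == "HC", "HC",
         ifelse(m$subgroup == "complications", "CVID_comp", "CVID_non"))
}
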