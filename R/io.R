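#' Read a spectral dataset from disk
#'
#' Two plain-text layouts are supported. `"wide_table"` is a single CSV
#' with the six metadata columns first (`subject_id`, `group`, `subgroup`,
#' `biofluid`, `spot`, `replicate`) followed by one numeric column per
#' wavenumber, named by the wavenumber value. `"per_spectrum_files"` is a
#' directory of two-column (wavenumber, absorbance) text files plus a
#' `manifest.csv` mapping each filename to its metadata.
#'
#' Axes written descending (display convention) are re-ordered ascending
#' on read, so a dataset and its reversed twin load identically.
#'
#' @param path File (wide table) or directory (per-spectrum files).
#' @param format `"wide_table"` or `"per_spectrum_files"`.
#' @return A [spectral_dataset()].
#' @export
read_dataset <- function(path, format = c("wide_table", "per_spectrum_files")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  if (format == "wide_table") read_wide_table(path) else read_per_spectrum(path)
}

meta_cols <- c("subject_id", "group", "subgroup", "biofluid", "spot", "replicate")

read_wide_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(meta_cols, names(df))
  if (length(missing_cols))
    stop("wide table lacks metadata column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  wn_names <- setdiff(names(df), meta_cols)
  wn <- suppressWarnings(as.numeric(wn_names))
  if (any(is.na(wn)))
    stop("non-numeric wavenumber column header(s): ",
         paste(wn_names[is.na(wn)][1:min(3, sum(is.na(wn)))], collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0)
    return(spectral_dataset(wn, matrix(numeric(0), 0, length(wn)),
                            empty_meta()))
  spectral_dataset(wn, as.matrix(df[, wn_names, drop = FALSE]),
                   df[, meta_cols])
}

empty_meta <- function() {
  data.frame(subject_id = character(0), group = character(0),
              subgroup = character(0), biofluid = character(0),
              spot = integer(0), replicate = integer(0))
}

read_per_spectrum <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path))
    stop("per-spectrum directory lacks manifest.csv", call. = FALSE)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!"filename" %in% names(man))
    stop("manifest lacks a filename column", call. = FALSE)
  missing_cols <- setdiff(meta_cols, names(man))
  if (length(missing_cols))
    stop("manifest lacks metadata column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  specs <- lapply(man$filename, function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("spectrum file missing: ", f, call. = FALSE)
    tab <- utils::read.table(p, header = FALSE,
                             sep = if (any(grepl(",", readLines(p, n = 1)))) "," else "")
    as.matrix(tab[, 1:2])
  })
  axis0 <- specs[[1]][, 1]
  if (length(axis0) >= 2 && axis0[1] > axis0[length(axis0)]) axis0 <- rev(axis0)
  mat <- t(vapply(specs, function(s) {
    wn <- s[, 1]; ab <- s[, 2]
    if (length(wn) >= 2 && wn[1] > wn[length(wn)]) { wn <- rev(wn); ab <- rev(ab) }
    if (length(wn) != length(axis0) || max(abs(wn - axis0)) > 1e-6 * max(abs(axis0)))
      stop("spectrum files do not share one wavenumber axis", call. = FALSE)
    ab
  }, numeric(length(axis0))))
  spectral_dataset(axis0, mat, man[, meta_cols])
}

#' Write a spectral dataset to disk
#'
#' Inverse of [read_dataset()]: `read_dataset(write_dataset(ds, p), ...)`
#' reproduces the axis, matrix and metadata. The wide table prints
#' wavenumber headers with up to 2 decimals and absorbances at full
#' double precision (17 significant digits) so the round trip is
#' bit-identical.
#'
#' @param ds A [spectral_dataset()].
#' @param path Output file (wide table) or directory (per-spectrum files).
#' @param format `"wide_table"` or `"per_spectrum_files"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, format = c("wide_table", "per_spectrum_files")) {
  format <- match.arg(format)
  validate_dataset(ds)
  if (format == "wide_table") {
    wn_names <- formatC(ds$wavenumbers, format = "f", digits = 2, drop0trailing = TRUE)
    header <- paste(c(meta_cols, wn_names), collapse = ",")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    if (nrow(ds$meta)) {
      m <- ds$meta
      vals <- apply(ds$absorbance, 1, function(r)
        paste(formatC(r, format = "g", digits = 17), collapse = ","))
      writeLines(paste(m$subject_id, m$group, m$subgroup, m$biofluid,
                       m$spot, m$replicate, vals, sep = ","), con)
    }
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    n <- nrow(ds$meta)
    files <- sprintf("spectrum_%04d.txt", seq_len(n))
    for (i in seq_len(n)) {
      utils::write.table(
        data.frame(wn = ds$wavenumbers,
                   ab = formatC(ds$absorbance[i, ], format = "g", digits = 17)),
        file.path(path, files[i]),
        row.names = FALSE, col.names = FALSE, quote = FALSE, sep = ",")
    }
    man <- cbind(data.frame(filename = files), ds$meta)
    utils::write.csv(man, file.path(path, "manifest.csv"), row.names = FALSE)
  }
  invisible(path)
}
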