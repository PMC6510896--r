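#' Rubber-band baseline correction
#'
#' Estimates the baseline of a spectrum as its lower convex hull: the
#' tightest convex chain stretched beneath the (wavenumber, absorbance)
#' points, anchored at the first and last point, linearly interpolated
#' between hull vertices. Subtracting it removes broad concave-up drift
#' while leaving band shapes intact; the corrected spectrum is
#' non-negative and touches zero at every hull vertex. The construction is
#' a single pass (Andrew's monotone chain), with no iteration or
#' wavenumber weighting.
#'
#' @param wavenumbers Ascending numeric axis (cm^-1), at least 3 points.
#' @param absorbance Numeric vector, same length.
#' @return A list with components `corrected` and `baseline`.
#' @export
#' @examples
#' wn <- seq(900, 1800, by = 4)
#' y <- exp(-(wn - 1300)^2 / 800) + 0.001 * (wn - 900)  # band on a sloped base
#' rb <- rubberband_baseline(wn, y)
#' min(rb$corrected)  # ~0
rubberband_baseline <- function(wavenumbers, absorbance) {
  n <- length(wavenumbers)
  if (n < 3) stop("rubber-band correction needs at least 3 points", call. = FALSE)
  if (length(absorbance) != n)
    stop("wavenumbers and absorbance differ in length", call. = FALSE)
  hull <- lower_hull_indices(wavenumbers, absorbance)
  baseline <- stats::approx(wavenumbers[hull], absorbance[hull],
                            xout = wavenumbers)$y
  list(corrected = absorbance - baseline, baseline = baseline)
}

# Lower convex hull of points already sorted by x (Andrew's monotone chain).
# Returns indices of hull vertices, always including both endpoints.
lower_hull_indices <- function(x, y) {
  n <- length(x)
  hull <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    # pop while the last two kept points and point i make a clockwise turn
    # or are collinear (cross product <= 0 keeps the hull minimal)
    while (top >= 2L) {
      a <- hull[top - 1L]; b <- hull[top]
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross <= 0) top <- top - 1L else break
    }
    top <- top + 1L
    hull[top] <- i
  }
  hull[seq_len(top)]
}

#' Vector normalisation
#'
#' Scales a spectrum to unit Euclidean norm. By default no mean is
#' subtracted first (`center = FALSE`); the mean-subtracting dialect used
#' by some acquisition software is available via `center = TRUE`.
#'
#' @param absorbance Numeric vector.
#' @param center Subtract the mean before scaling?
#' @return The normalised vector (unit 2-norm).
#' @export
vector_normalize <- function(absorbance, center = FALSE) {
  x <- if (center) absorbance - mean(absorbance) else absorbance
  nrm <- sqrt(sum(x^2))
  # threshold rather than exact zero: a baseline-corrected straight line
  # leaves only rounding residue, which must not be blown up to unit norm
  if (nrm < sqrt(length(x)) * 1e-11)
    stop("cannot vector-normalise an (effectively) all-zero spectrum",
         call. = FALSE)
  x / nrm
}

#' Savitzky-Golay smoothing and differentiation
#'
#' Fits a local least-squares polynomial of order `polyorder` within a
#' sliding window of `window` points and evaluates its `deriv`-th
#' derivative at the window centre. Derivatives are taken with respect to
#' cm^-1 on the ascending axis (scaled by the axis spacing). The first and
#' last `(window - 1) / 2` points are evaluated from the polynomial fit of
#' the nearest full window, so the output keeps the input length.
#'
#' @param absorbance Numeric vector, length >= `window`.
#' @param spacing Axis spacing in cm^-1 (default 4, the instrument's data
#'   spacing after zero-filling).
#' @param window Odd number of filter coefficients (> `polyorder`).
#' @param polyorder Polynomial order.
#' @param deriv Derivative order (0 = smoothing), <= `polyorder`.
#' @return Numeric vector, same length as the input.
#' @export
savitzky_golay <- function(absorbance, spacing = 4, window = 9,
                           polyorder = 2, deriv = 0) {
  if (window %% 2 != 1) stop("window must be odd", call. = FALSE)
  if (window <= polyorder) stop("window must exceed polyorder", call. = FALSE)
  if (deriv > polyorder) stop("deriv must not exceed polyorder", call. = FALSE)
  if (length(absorbance) < window)
    stop("spectrum shorter than the filter window", call. = FALSE)
  as.numeric(signal::sgolayfilt(absorbance, p = polyorder, n = window,
                                m = deriv, ts = spacing))
}

#' Preprocessing recipe
#'
#' The two preprocessing variants used for biofluid spectra:
#' * `"rubberband"` (variant A): rubber-band baseline correction followed
#'   by vector normalisation; keeps absorbance bands positively peaked,
#'   used for visual comparison and band-intensity analysis.
#' * `"sg2d"` (variant B): Savitzky-Golay second derivative (the
#'   derivative itself serving as baseline correction and de-noising)
#'   followed by vector normalisation; sharpens overlapping bands, used
#'   for classification.
#'
#' @param variant `"rubberband"` or `"sg2d"`.
#' @param sg_window Odd filter length for the Savitzky-Golay filter
#'   (default 9 coefficients).
#' @param sg_polyorder Polynomial order (default 2).
#' @param center Mean-subtract before vector normalisation? Default
#'   `FALSE` (plain unit-norm scaling).
#' @return An object of class `preprocess_recipe`.
#' @export
preprocess_recipe <- function(variant = c("rubberband", "sg2d"),
                              sg_window = 9, sg_polyorder = 2,
                              center = FALSE) {
  variant <- match.arg(variant)
  if (sg_window %% 2 != 1 || sg_window <= sg_polyorder)
    stop("sg_window must be odd and exceed sg_polyorder", call. = FALSE)
  structure(list(variant = variant, sg_window = sg_window,
                 sg_polyorder = sg_polyorder,
                 sg_deriv = if (variant == "sg2d") 2L else 0L,
                 center = center),
            class = "preprocess_recipe")
}

#' @export
print.preprocess_recipe <- function(x, ...) {
  cat("preprocess_recipe:",
      if (x$variant == "rubberband")
        "rubber-band baseline + vector normalisation"
      else sprintf("Savitzky-Golay 2nd derivative (window %d, order %d) + vector normalisation",
                   x$sg_window, x$sg_polyorder), "\n")
  invisible(x)
}

#' Apply a preprocessing recipe to a dataset
#'
#' Applies the recipe spectrum by spectrum; the wavenumber axis and the
#' metadata are untouched, so region extraction commutes with
#' preprocessing order-independently at the record level.
#'
#' @param ds A [spectral_dataset()].
#' @param recipe A [preprocess_recipe()].
#' @return A `spectral_dataset` of preprocessed spectra.
#' @export
apply_recipe <- function(ds, recipe) {
  validate_dataset(ds)
  stopifnot(inherits(recipe, "preprocess_recipe"))
  wn <- ds$wavenumbers
  spacing <- if (length(wn) > 1) wn[2] - wn[1] else 1
  out <- t(apply(ds$absorbance, 1, function(y) {
    z <- if (recipe$variant == "rubberband")
      rubberband_baseline(wn, y)$corrected
    else
      savitzky_golay(y, spacing = spacing, window = recipe$sg_window,
                     polyorder = recipe$sg_polyorder, deriv = 2)
    vector_normalize(z, center = recipe$center)
  }))
  if (nrow(ds$absorbance) == 1L) out <- matrix(out, nrow = 1L)
  structure(list(wavenumbers = wn, absorbance = out, meta = ds$meta),
            class = "spectral_dataset")
}
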