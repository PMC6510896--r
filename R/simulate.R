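#' Simulation configuration for synthetic biofluid spectra
#'
#' Describes a synthetic ATR-FTIR study: group sizes, replicate
#' structure, wavenumber axis, a library of Gaussian absorption bands, a
#' table of class-dependent band-intensity effects, and the noise model
#' (between-subject band-amplitude variability, within-subject replicate
#' noise, and a random low-order polynomial baseline per replicate).
#'
#' @param n_hc,n_cvid_non,n_cvid_comp Subject counts: healthy controls,
#'   complication-free CVID patients, CVID patients with complications.
#' @param spots,points_per_spot Replicate structure: spectra are acquired
#'   at `points_per_spot` locations on each of `spots` dried-biofluid
#'   spots (defaults 2 x 10 = 20 replicates per subject per biofluid).
#' @param axis Wavenumber axis (default 400-4000 cm^-1 at 4 cm^-1
#'   spacing, the instrument's data spacing after zero-filling).
#' @param band_library Data frame with columns `center` (cm^-1), `width`
#'   (Gaussian sigma, cm^-1) and `base_amplitude` (absorbance units).
#' @param effects Data frame with columns `wavenumber` (must match a band
#'   center), `delta` (additive amplitude change in CVID subjects) and
#'   `subgroup_scale` (multiplier on `delta` for the complications
#'   subgroup).
#' @param subject_sd Between-subject SD of each band amplitude.
#' @param center_sd Between-subject SD of each band's centre position
#'   (cm^-1): dried-film spectra of different subjects show small band
#'   shifts from compositional differences, which decorrelate band flanks
#'   across subjects.
#' @param replicate_sd Within-subject per-point noise SD.
#' @param baseline_range Half-range of the uniform draws for the three
#'   coefficients of the per-replicate quadratic baseline drift.
#' @param biofluid `"serum"` or `"plasma"` (label carried in metadata).
#' @param seed Integer seed; the generator is fully reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_hc = 30, n_cvid_non = 8, n_cvid_comp = 13,
                       spots = 2, points_per_spot = 10,
                       axis = seq(400, 4000, by = 4),
                       band_library = default_band_library(),
                       effects = default_effects(),
                       subject_sd = 0.004, center_sd = 1.0,
                       replicate_sd = 0.002,
                       baseline_range = 0.02,
                       biofluid = "serum", seed = 1L) {
  if (n_hc < 0 || n_cvid_non < 0 || n_cvid_comp < 0)
    stop("subject counts must be non-negative", call. = FALSE)
  if (spots < 1 || points_per_spot < 1)
    stop("replicate structure must be at least 1 spot x 1 point", call. = FALSE)
  stopifnot(all(c("center", "width", "base_amplitude") %in% names(band_library)),
            all(band_library$width > 0), all(band_library$base_amplitude >= 0))
  if (nrow(effects)) {
    stopifnot(all(c("wavenumber", "delta", "subgroup_scale") %in% names(effects)))
    off <- setdiff(effects$wavenumber, band_library$center)
    if (length(off))
      stop("effect wavenumber(s) without a matching band: ",
           paste(off, collapse = ", "), call. = FALSE)
  }
  structure(list(n_hc = n_hc, n_cvid_non = n_cvid_non,
                 n_cvid_comp = n_cvid_comp, spots = spots,
                 points_per_spot = points_per_spot, axis = axis,
                 band_library = band_library, effects = effects,
                 subject_sd = subject_sd, center_sd = center_sd,
                 replicate_sd = replicate_sd,
                 baseline_range = baseline_range, biofluid = biofluid,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default absorption band library
#'
#' Gaussian bands emulating a dried serum/plasma film: the dominant
#' Amide I and II protein bands, Amide III, the asymmetric phosphate
#' stretch, carbohydrate/phosphodiester bands across 980-1170 cm^-1, the
#' triglyceride ester carbonyl, the CH-stretch cluster at 2850-2960
#' cm^-1, and a broad O-H/N-H envelope near 3300 cm^-1.
#'
#' @return Data frame with columns `center`, `width`, `base_amplitude`.
#' @export
default_band_library <- function() {
  data.frame(
    center         = c(984, 1034, 1080, 1115, 1160, 1242, 1315, 1400,
                       1454, 1528, 1535, 1643, 1759, 2850, 2874, 2930,
                       2958, 3070, 3300),
    width          = c(8, 10, 12, 9, 10, 14, 12, 15,
                       10, 10, 14, 18, 8, 12, 10, 15,
                       10, 25, 120),
    base_amplitude = c(0.08, 0.12, 0.10, 0.10, 0.06, 0.14, 0.10, 0.12,
                       0.10, 0.08, 0.28, 0.45, 0.04, 0.08, 0.05, 0.12,
                       0.07, 0.08, 0.35))
}

#' Default class-effect table
#'
#' Six fingerprint-region bands whose amplitude differs between CVID
#' patients and controls, in the directions reported for serum biofluid
#' spectra: increases at the phosphodiester/collagen-associated bands
#' (984, 1034, 1115 cm^-1) and the triglyceride ester band (1759 cm^-1),
#' decreases at the asymmetric phosphate stretch (1242 cm^-1) and the
#' nucleotide-base-associated band (1528 cm^-1). Effects are accentuated
#' by half again in the complications subgroup.
#'
#' @return Data frame with columns `wavenumber`, `delta`, `subgroup_scale`.
#' @export
default_effects <- function() {
  data.frame(
    wavenumber     = c(984, 1034, 1115, 1242, 1528, 1759),
    delta          = c(0.010, 0.012, 0.010, -0.008, -0.005, 0.006),
    subgroup_scale = rep(1.5, 6))
}

#' Null variant of a simulation configuration
#'
#' Returns the configuration with every effect delta set to zero, so the
#' two classes are generated from identical distributions
#' (exchangeable): the reference for type-I-error and permutation
#' checks. Counts, noise and seed are preserved; the operation is
#' idempotent.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_config` with zeroed effects.
#' @export
null_variant <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cfg$effects$delta <- rep(0, nrow(cfg$effects))
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$n_hc, " HC + ", x$n_cvid_non, " CVID-non + ",
      x$n_cvid_comp, " CVID-comp subjects, ",
      x$spots, "x", x$points_per_spot, " replicates, axis ",
      min(x$axis), "-", max(x$axis), " cm-1 (", length(x$axis),
      " points), ", nrow(x$band_library), " bands, ",
      sum(x$effects$delta != 0), " active effect(s), seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic spectral dataset with known ground truth
#'
#' Draws one dataset from the configured study. Per subject, each band's
#' amplitude is `base_amplitude` + class effect (delta, scaled by
#' `subgroup_scale` in the complications subgroup) + Normal(0,
#' `subject_sd`), and its centre is displaced by Normal(0, `center_sd`)
#' cm^-1. Per replicate spectrum, the Gaussian bands are summed
#' and a random quadratic baseline plus Normal(0, `replicate_sd`)
#' per-point noise is added. Subject draws are seeded hierarchically from
#' the global seed, so enlarging the cohort leaves the spectra of earlier
#' subjects unchanged.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_result`: `dataset` (a
#'   [spectral_dataset()]) and `truth` (the implanted effects with
#'   direction, the seed, and the per-group subject ids).
#' @export
#' @examples
#' sim <- simulate_spectra(sim_config(n_hc = 3, n_cvid_non = 1,
#'                                    n_cvid_comp = 2, seed = 7))
#' sim$dataset
simulate_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  axis <- cfg$axis
  bl <- cfg$band_library
  n_bands <- nrow(bl)
  groups <- c(rep("HC", cfg$n_hc), rep("CVID", cfg$n_cvid_non),
              rep("CVID", cfg$n_cvid_comp))
  subgroups <- c(rep("none_assigned", cfg$n_hc),
                 rep("complication_free", cfg$n_cvid_non),
                 rep("complications", cfg$n_cvid_comp))
  n_subj <- length(groups)
  ids <- sprintf("S%03d_%s", seq_len(n_subj),
                 ifelse(groups == "HC", "HC",
                        ifelse(subgroups == "complications", "CVc", "CVn")))
  # per-subject effect vector over bands
  eff <- numeric(n_bands)
  n_rep <- cfg$spots * cfg$points_per_spot
  mats <- vector("list", n_subj)
  meta <- vector("list", n_subj)
  t_axis <- (axis - min(axis)) / max(1, diff(range(axis)))
  for (i in seq_len(n_subj)) {
    old <- local_seed(sub_seed(cfg$seed, i))
    amp_eff <- bl$base_amplitude
    if (nrow(cfg$effects) && groups[i] == "CVID") {
      scale_i <- ifelse(subgroups[i] == "complications",
                        cfg$effects$subgroup_scale, 1)
      j <- match(cfg$effects$wavenumber, bl$center)
      amp_eff[j] <- amp_eff[j] + cfg$effects$delta * scale_i
    }
    amps <- amp_eff + stats::rnorm(n_bands, 0, cfg$subject_sd)
    amps <- pmax(amps, 0)
    centers <- bl$center + stats::rnorm(n_bands, 0, cfg$center_sd)
    base_coef <- matrix(stats::runif(3 * n_rep, -cfg$baseline_range,
                                     cfg$baseline_range), n_rep, 3)
    noise <- matrix(stats::rnorm(n_rep * length(axis), 0, cfg$replicate_sd),
                    n_rep, length(axis))
    restore_seed(old)
    profiles <- exp(-(outer(centers, axis, `-`) / bl$width)^2 / 2)
    clean <- as.numeric(amps %*% profiles)
    baselines <- base_coef %*% rbind(1, t_axis, t_axis^2)
    mats[[i]] <- matrix(clean, n_rep, length(axis), byrow = TRUE) +
      baselines + noise
    meta[[i]] <- data.frame(
      subject_id = ids[i], group = groups[i], subgroup = subgroups[i],
      biofluid = cfg$biofluid,
      spot = rep(seq_len(cfg$spots), each = cfg$points_per_spot),
      replicate = rep(seq_len(cfg$points_per_spot), cfg$spots),
      stringsAsFactors = FALSE)
  }
  ds <- spectral_dataset(axis, do.call(rbind, mats), do.call(rbind, meta))
  truth <- list(
    effects = if (nrow(cfg$effects))
      cbind(cfg$effects,
            direction = ifelse(cfg$effects$delta >= 0,
                               "up_in_CVID", "down_in_CVID"))
    else cfg$effects,
    seed = cfg$seed,
    subjects = data.frame(subject_id = ids, group = groups,
                          subgroup = subgroups, stringsAsFactors = FALSE))
  structure(list(dataset = ds, truth = truth), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result (seed ", x$truth$seed, ")\n", sep = "")
  print(x$dataset)
  n_eff <- if (nrow(x$truth$effects)) sum(x$truth$effects$delta != 0) else 0
  cat("  implanted effects:", n_eff, "\n")
  invisible(x)
}
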