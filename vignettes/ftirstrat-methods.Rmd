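---
title: "Methods: chemometric stratification of biofluid ATR-FTIR spectra"
author: "ftirstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemometric stratification of biofluid ATR-FTIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirstrat)
```

## The problem

Common variable immunodeficiency (CVID) has no pathognomonic laboratory
marker; diagnosis is by exclusion, typically years after onset. Infrared
absorbance spectra of dried serum or plasma films integrate the
biochemical composition of the sample into a single curve, and
multivariate analysis of such spectra can separate patients from healthy
controls (HC) and point to the wavenumbers — hence the molecular species
— that drive the separation. `ftirstrat` implements this pipeline:
container and I/O for replicate-structured spectral datasets,
the two standard preprocessing recipes, PCA-LDA with
leave-one-subject-out cross-validation, patient-level Kennard-Stone
splitting with radial-kernel SVM classification, three spectral
biomarker extraction methods with peak detection and proximity
filtering, subject-level band-intensity statistics, and a synthetic
spectrum generator with known ground truth against which every stage is
validated.

## Data model

A `spectral_dataset` couples one ascending, uniformly spaced wavenumber
axis (cm^-1) with an `n x p` absorbance matrix and per-spectrum
metadata: subject, group (HC/CVID), clinical subgroup (with/without
complications, CVID only), biofluid (serum/plasma), and the replicate
structure — 2 dried spots x 10 acquisition points = 20 replicate spectra
per subject per biofluid. Replicates are not independent observations:
`average_replicates()` collapses them to one spectrum per subject
(sentinel `spot = replicate = 0`), and every statistical routine in the
package operates at subject level unless explicitly asked otherwise.
Analysis is restricted to the fingerprint region (900–1800 cm^-1) or the
high region (2800–3700 cm^-1); both interval endpoints are included.

## Preprocessing

Two recipes, applied spectrum by spectrum after replicate averaging:

* **Variant A — rubber-band + vector normalisation.** The baseline is
  the lower convex hull of the (wavenumber, absorbance) points, anchored
  at the endpoints and linearly interpolated between hull vertices
  (single pass, no iteration, no wavenumber weighting). Subtraction
  leaves a non-negative spectrum that touches zero at every hull vertex.
  Band positions and positive intensities are preserved, so this variant
  feeds visual comparison and band-intensity statistics.
* **Variant B — Savitzky-Golay second derivative.** A second-order
  polynomial, nine filter coefficients, differentiating twice with
  respect to cm^-1 on the ascending axis. The derivative itself acts as
  baseline removal and band sharpening; this variant feeds
  classification. The first and last four points are evaluated from the
  polynomial fit of the nearest full window, keeping the axis length
  constant so region extraction commutes with filtering.

Both recipes end with vector normalisation to unit Euclidean norm.
The mean-subtracting dialect used by some acquisition software is
available (`center = TRUE`) but is not the default: plain unit-norm
scaling is idempotent, scale-invariant and the more common chemometrics
convention. A spectrum whose norm falls below `sqrt(p) * 1e-11` — for
example a straight line after baseline removal, where only rounding
residue remains — is rejected as degenerate rather than blown up to
unit norm.

## PCA-LDA

`pcalda()` is the package's central model object. The spectra are
decomposed by centred SVD; principal components are ordered by explained
variance and carry a deterministic sign (largest-magnitude loading
element positive). Fisher linear discriminant analysis is then performed
on the retained scores: with two classes the discriminant direction is
`Sw^-1 (m1 - m2)` with the pooled within-class covariance `Sw`
regularised by a ridge of `1e-8` of its trace; with three or more
classes the leading eigenvector of `Sw^-1 Sb` is used. LD1 is oriented
so the lexicographically first class label projects positive, making
fits invariant to row order.

The number of retained PCs defaults to the smallest count explaining at
least 99% of the variance, capped at (number of subjects − 2) so that
LDA never sees more dimensions than it has subjects to estimate them
from.

Cross-validation is leave-one-subject-out: all spectra of the held-out
subject are removed, PCA *and* LDA are refitted from scratch, and the
held-out spectra are projected through the refitted model. Replicates of
one subject are strongly correlated, so spectrum-level folds would leak;
subject-level folds do not. A Welch two-tailed t-test on the
cross-validated LD1 scores of the two classes summarises separation.

**Cluster vectors.** The LD1 weight vector is back-projected through the
PCA loadings into wavenumber space; the absolute back-projection (the
*discriminant track*) measures how strongly each wavenumber drives the
separation, and each class gets a pseudo-spectrum scaled by its mean LD1
score. For this track, `cluster_vector_track()` defaults to 10 PCs
rather than the 99% rule: LD1 weight assigned to low-variance components
back-projects into unstructured wavenumber noise that drowns the
class-difference bands, and ten dominant components is the usual
biospectroscopy operating point. (The 99% default remains in place for
`pcalda()` scores and p-values, where cross-validation guards against
over-projection.)

## Classification

* **Split.** The Kennard-Stone algorithm runs per class on
  subject-averaged preprocessed spectra: the two mutually most distant
  subjects seed the training set, then subjects join by the max-min
  Euclidean rule until `round(fraction * n_class)` are selected
  (default fraction 2/3; at least one test subject is always kept). The
  split is deterministic and subjects never straddle the boundary.
* **Tuning.** A radial-kernel SVM is tuned over (cost, gamma) grids —
  defaults `2^-5..2^15` and `2^-15..2^3` in powers of four — by
  subject-grouped, class-stratified k-fold cross-validation accuracy on
  the training spectra. k defaults to 10; the grouped design exists
  because replicate spectra in separate folds would leak. Ties break
  toward the smallest cost, then the smallest gamma (the smoother
  model), so the result does not depend on grid ordering.
* **Evaluation.** The SVM is trained on all training spectra and
  predicts every test spectrum; sensitivity and specificity are computed
  from the accumulated spectrum-level hits (TP/(TP+FN), TN/(TN+FP)),
  with CVID as the positive class. In three-class mode (HC /
  complication-free CVID / CVID with complications) each class is scored
  one-vs-rest. A true class absent from the test set yields `NA` with an
  explicit flag, never a silent zero.

## Biomarker extraction

Three feature-score tracks are computed on the (subject-averaged)
training spectra:

* **t-test track** — per-wavenumber two-tailed Welch t-test between
  classes; score `-log10(p)`. Subject averaging first is essential:
  pseudo-replicated spectrum-level tests overstate significance roughly
  by the replicate count. A spectrum-level mode and a pooled-variance
  variant exist for comparison. Axis points with zero variance in both
  groups (e.g. the two endpoints pinned to exactly zero by the
  rubber-band anchor) score 0 rather than NaN.
* **cluster-vector track** — the absolute LD1 back-projection above.
* **FFS track** — bootstrap forward feature selection. The candidate
  pool is the 60 wavenumbers with the largest variance-weighted
  aggregate |PCA loading|. In each bootstrap round (subjects resampled
  within class), candidates are admitted in order of increasing
  univariate Welch p-value, skipping any candidate within 20 cm^-1
  (about two band widths) of one already admitted, until six are
  selected; the track records selection counts across rounds. An
  alternative formulation — gating each admission on whether it improves
  the p-value of the multivariate Fisher projection of the current set —
  was implemented and rejected: on resampled data the in-sample
  projection p-value improves for almost any added column, so selection
  was driven by overfitting rather than class information, and implanted
  bands were not recovered.

`detect_peaks()` turns a track into a panel: local maxima (strictly
above both neighbours; plateaus contribute their lowest wavenumber;
endpoints qualify against their single neighbour) are ranked by height
and greedily retained, discarding any candidate within 10 cm^-1 of a
retained peak — neighbouring wavenumbers ride on the same band and carry
no independent information — up to six peaks per method.
`merge_panels()` unions the per-method panels, flags wavenumbers found
by two or more methods as corroborated, and applies the same 10 cm^-1
rule across methods, keeping the higher-scoring representative and
recording every omission.

`subject_intensity_analysis()` then compares, per biomarker and group
contrast (HC–CVID, HC–CVID-non, HC–CVID-comp, CVID-non–CVID-comp), the
subjects' mean variant-A intensities with Welch t-tests and 95%
confidence intervals; sample size is the number of subjects. No
multiple-testing correction is applied by default, matching the raw
p ≤ 0.05 reporting convention of subject-level band analyses;
`p.adjust` can be applied to the returned columns by the user.

`power_min_n()` finds the smallest group sizes (optionally at a fixed
allocation ratio such as 30:21) whose two-tailed two-sample t-test
reaches a target power under the noncentral-t model with
Welch–Satterthwaite degrees of freedom, verifying minimality at one
subject fewer.

## The synthetic study

`sim_config()` describes a synthetic cohort whose defaults mirror the
study design the package targets: 30 HC and 21 CVID subjects (8
complication-free, 13 with complications), 2 spots x 10 points = 20
replicate spectra per subject per biofluid, axis 400–4000 cm^-1 at
4 cm^-1 spacing. Spectra are sums of Gaussian bands from a 19-band
library (Amide I/II/III, the asymmetric phosphate stretch,
carbohydrate/phosphodiester bands, the triglyceride ester carbonyl, the
CH-stretch cluster and a broad O–H/N–H envelope), plus a random
quadratic baseline and white replicate noise.

Per subject, each band's amplitude is drawn as
`base + class effect + N(0, subject_sd)` and its centre is displaced by
`N(0, center_sd)` cm^-1. The centre jitter matters: with amplitude noise
alone, every point across a band's span is perfectly correlated within
subject, so a t-statistic track is flat-topped across the whole band and
its maxima land on band flanks; real dried-film spectra show small
compositional band shifts between subjects, which suppress the flanks
and localise the track maximum at the band centre.

The default effect table implants the six fingerprint-region
differences reported for serum: increases at 984, 1034, 1115 and
1759 cm^-1, decreases at 1242 and 1528 cm^-1, each amplified 1.5x in
the complications subgroup. Published sources give directions and
significance but no effect magnitudes, so the deltas are synthetic
choices, set once to satisfy two constraints: (i) subject-level
significance at the cohort's 30/21 sizes, and (ii) an approximately
norm-balanced total (increases and decreases cancelling in the vector
norm), so that normalisation does not redistribute a net intensity
change onto unaffected bands. Noise scales are `subject_sd = 0.004`
absorbance per band, `center_sd = 1.0` cm^-1, `replicate_sd = 0.002`
per point, baseline coefficients uniform in ±0.02 — values at which the
implanted effects have per-band standardised differences around 1.5–3,
large enough for a 51-subject study to detect reliably and small enough
that single spectra overlap between classes.

Generation is hierarchically seeded: each subject's draws derive from
the global seed and the subject index, so enlarging the cohort leaves
earlier subjects' spectra bit-identical. `null_variant()` zeroes every
delta, making the classes exchangeable — the reference for type-I error
and permutation checks.

**What the generator does not emulate:** Mie scattering, water-vapour
lines, detector drift, coffee-ring spatial heterogeneity, non-Gaussian
line shapes, and correlated biochemical variation across bands. Passing
tests therefore demonstrate that the algorithms recover known ground
truth under a realistic noise budget — not that any particular
sensitivity will be attained on real cohorts, where unmodelled
variation sources and unreported analysis choices (exact PC counts,
fold structure) move headline rates by several points.

## Calibration and validation choices

* Under the null configuration, an SVM trained on uninformative spectra
  predicts mostly the majority class, so raw per-class rates sit near
  100%/0% rather than 50%/50%. The calibration check therefore uses
  balanced accuracy (the mean of the two per-class rates), whose
  expectation is exactly 0.5 whenever predictions are independent of the
  true labels, regardless of classifier bias.
* Oracle tests compare the rubber band against an O(n^3) exhaustive
  chord search, the Savitzky-Golay filter against per-window
  least-squares fits, Kennard-Stone against brute-force max-min
  reselection, PCA-LDA against direct Fisher LDA on full-rank toys (and
  `MASS::lda`), and the power search against a 1e5-draw Monte-Carlo
  simulation.
* Test problem sizes: ground-truth recovery uses 50 independent
  replicates of the full 51-subject study; null classification uses 50
  replicates with a compact tuning grid; the t-test level check uses
  100 null runs of 1000 wavenumbers at group sizes 30/21. These sizes
  give binomial noise comfortably below the margins being asserted.

## Limitations

* The package deliberately implements no scatter correction (EMSC/SNV)
  or water-vapour compensation; spectra needing them must be corrected
  upstream.
* Vendor binary formats (OPUS, JCAMP-DX) are out of scope; data enter
  as wide CSV tables or two-column text files with a manifest.
* FFS internals differ between published toolboxes; the formulation here
  (documented above) reproduces selection-count histogram semantics but
  is not a re-implementation of any specific toolbox.
* Sensitivities and specificities quoted for real cohorts depend on
  unreported choices (PC count, fold scheme, FFS details) and are not
  expected to be reproduced exactly by any independent implementation.
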