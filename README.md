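# ftirstrat

Chemometric stratification of biofluid ATR-FTIR spectra.

Attenuated total reflection Fourier-transform infrared (ATR-FTIR)
spectroscopy of dried serum or plasma films yields an absorbance curve
over wavenumber (cm⁻¹) that integrates the biochemical composition of a
blood sample. For disorders without a pathognomonic laboratory marker —
the motivating case is common variable immunodeficiency (CVID), a
primary antibody deficiency diagnosed by exclusion — multivariate
analysis of such spectra can separate patients from healthy controls
(HC) and localise the wavenumbers that drive the separation, pointing to
candidate molecular biomarkers.

`ftirstrat` is aimed at spectroscopists and clinical researchers running
this kind of case–control study. It provides the full pipeline:

* **Spectral data handling** — a validated container for
  replicate-structured datasets (subjects × 2 spots × 10 points), wide-CSV
  and per-file I/O, replicate averaging, fingerprint (900–1800 cm⁻¹) and
  high (2800–3700 cm⁻¹) region extraction.
* **Preprocessing** — rubber-band (lower convex hull) baseline
  correction, Savitzky–Golay second derivatives (order 2, 9
  coefficients), and vector normalisation.
* **PCA-LDA** — Fisher's linear discriminant on principal-component
  scores. For spectra *x*, PCA gives scores *t* = *L*(*x* − *x̄*); LD1
  maximises the Fisher criterion *w*ᵀ*S*_B *w* / *w*ᵀ*S*_W *w* on those
  scores, with leave-one-subject-out cross-validated scores and a
  cluster-vector back-projection |*w*ᵀ*L*| that scores every wavenumber's
  contribution to the separation.
* **Classification** — deterministic patient-level Kennard–Stone
  train/test splitting, RBF-kernel SVM with (cost, γ) grid search under
  subject-grouped stratified k-fold cross-validation, and
  sensitivity/specificity from accumulated spectrum-level hits.
* **Biomarker extraction** — per-wavenumber Welch t-test tracks,
  cluster-vector tracks, and bootstrap forward feature selection; peak
  detection with a 10 cm⁻¹ proximity filter; cross-method panel merging
  with corroboration flags; subject-level band-intensity contrasts with
  95% CIs; minimum-sample-size search for a two-sample t-test under the
  noncentral-t model.
* **Synthetic data** — a seeded generator of ATR-FTIR-like datasets with
  known implanted class effects, emulating the 30 HC / 21 CVID (8
  complication-free, 13 with complications) study design, so every stage
  is testable against ground truth.

See `vignettes/ftirstrat-methods.Rmd` for the modelling decisions and
their rationale.

## Worked example

```r
library(ftirstrat)

sim <- simulate_spectra(sim_config(seed = 1))   # default synthetic study
sim$dataset
#> spectral_dataset: 1020 spectra, 901 wavenumbers (400-4000 cm-1, step 4)
#>   subjects: 51 | groups: CVID=420 HC=600 | biofluids: serum

res <- run_classification(sim$dataset, region = "fingerprint",
  cfg = svm_config(c_grid = 4^(0:3), gamma_grid = 4^(-4:0),
                   folds = 5, seed = 1))
res
#> classification_result: region=fingerprint, labelling=two_class, SVM cost=64 gamma=1 (CV acc 100.0%)
#> confusion_report (340 spectra)
#>       predicted
#> true    HC CVID
#>   HC   200    0
#>   CVID   1  139
#> per-class correct (%): HC=100.0  CVID=99.3
#> sensitivity (CVID) = 99.3%, specificity = 100.0%
```

The dataset is 51 subjects × 20 replicate spectra. `run_classification`
preprocesses (Savitzky–Golay second derivative + vector normalisation),
extracts the fingerprint region, splits subjects 2/3–1/3 by
Kennard–Stone, grid-searches the SVM on the 31 training subjects and
reports the 340 test spectra (20 HC and 7 CVID subjects): 339 of 340 are
assigned to the correct group, i.e. the implanted class effects are
large enough to classify almost perfectly at this noise level.

Biomarker extraction on the same study recovers the implanted panel:

```r
pp <- select_region(apply_recipe(average_replicates(sim$dataset),
                                 preprocess_recipe("rubberband")),
                    "fingerprint")
panel <- merge_panels(list(
  detect_peaks(ttest_track(pp, subject_average = FALSE)),
  detect_peaks(cluster_vector_track(pp)),
  detect_peaks(ffs_track(pp, rounds = 100, seed = 1))))
panel$peaks[, c("wavenumber", "methods", "n_methods", "direction")]
#>  wavenumber                  methods n_methods    direction
#>         984 cluster_vector,ffs,ttest         3   up_in_CVID
#>        1036 cluster_vector,ffs,ttest         3   up_in_CVID
#>        1116 cluster_vector,ffs,ttest         3   up_in_CVID
#>        1244 cluster_vector,ffs,ttest         3 down_in_CVID
#>        1536                      ffs         1         <NA>
#>        1648                      ffs         1         <NA>
#>        1760     cluster_vector,ttest         2   up_in_CVID
```

Five of the six implanted effect bands (984, 1034, 1115, 1242,
1759 cm⁻¹; the weak 1528 cm⁻¹ band is missed here in favour of two
uncorroborated FFS picks) appear within one or two axis steps of their
true centres and are corroborated by at least two of the three methods,
with the implanted directions of change.

A command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","ftirstrat.R",package="ftirstrat"))')" \
    simulate --seed 3 --out out/      # writes dataset.csv + truth.json
# ... classify --data out/dataset.csv --region fingerprint --seed 3 --out out/
# ... run-all  --seed 3 --out out/    # full pipeline report
```

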