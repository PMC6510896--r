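Package: ftirstrat
Title: Chemometric Stratification of Biofluid ATR-FTIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for classifying subjects from attenuated total
    reflection Fourier-transform infrared (ATR-FTIR) spectra of serum or
    plasma. Implements rubber-band (lower convex hull) baseline
    correction, Savitzky-Golay second-derivative preprocessing and vector
    normalisation; principal component analysis followed by Fisher linear
    discriminant analysis (PCA-LDA) with leave-one-subject-out
    cross-validation and cluster-vector back-projection; patient-level
    Kennard-Stone train/test splitting; radial-kernel support vector
    machine classification with grid-searched tuning parameters;
    spectral biomarker extraction by per-wavenumber t-tests,
    cluster vectors and forward feature selection, with peak detection
    and proximity filtering; subject-level band-intensity comparisons and
    two-sample t-test power calculations; and a synthetic spectrum
    generator with known ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
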