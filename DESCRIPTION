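Package: dcaflow
Title: Dynamic Cerebral Autoregulation Models and Wavelet Statistical Complexity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the dynamic relationship between arterial blood
    pressure and cerebral blood flow velocity. Implements the standard
    preprocessing chain for beat-to-beat hemodynamic recordings (spline gap
    repair, Hampel outlier removal, zero-phase low-pass filtering, beat
    detection and averaging, uniform resampling, min-max normalization);
    dynamic FIR/NFIR/ARX/NARX models of the pressure-to-flow relationship
    fitted by nu-support-vector regression with free-run validation and grid
    search; autoregulation index (ARI) estimation by matching model step
    responses to the ten Tiecks second-order templates under physiological
    plausibility criteria; wavelet relative-energy entropy, disequilibrium and
    Lopez-Ruiz statistical complexity with complexity-entropy plane
    coordinates; cohort-level statistics (Shapiro-Wilk, paired tests,
    repeated-measures ANOVA with Tukey post hoc, ROC/AUC); and a synthetic
    hemodynamics generator (pulsatile pressure plus Tiecks-model flow velocity
    at known ARI grades) so that every stage can be exercised offline with
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
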