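Package: petquant
Title: Quantitative Small-Animal PET Tumor Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An operator-independent pipeline for quantitative analysis of
    small-animal FDG-PET tumor scans. Converts reconstructed activity volumes
    to standardized uptake value (SUV) images, segments the metabolic tumor
    volume (MTV) with a deterministic region-based active-surface method,
    applies lesion admissibility checks (sphericity and uptake uniformity),
    corrects partial-volume losses with recovery coefficients indexed by
    sphere-equivalent diameter, computes SUVmean, SUVmax and total lesion
    glycolysis (TLG), and classifies longitudinal metabolic response with
    EORTC-style percentage-change thresholds. Includes a synthetic-phantom
    generator with known ground truth for end-to-end validation, a
    semi-quantitative immunohistochemistry scoring module (intensity,
    extent and immunoreactivity scores; per-10-high-power-field counts),
    and the group-comparison decision tree (Shapiro-Wilk normality,
    variance homogeneity, t-test/ANOVA with Holm-Sidak or Kruskal-Wallis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    car,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
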