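Package: qsmoef
Title: Quantitative Susceptibility Mapping and Venous Oxygen Extraction
    Fraction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the cerebral oxygen extraction fraction
    (OEF) from gradient-echo MRI phase via quantitative susceptibility
    mapping (QSM).  Provides a susceptibility phantom simulator with
    paramagnetic cylindrical veins of known oxygenation and a forward
    dipole model; a QSM reconstruction chain (phase normalization,
    Laplacian phase unwrapping, V-SHARP background-field removal with
    variable spherical-mean-value kernels and TSVD deconvolution, and
    thresholded k-space division with a two-pass strong-source variant
    to suppress streaking); vein-based sliding-window OEF mapping from
    the susceptibility contrast between veins and surrounding tissue;
    region-of-interest summaries against an integer label volume; and
    the two-group statistics (normality-gated t / Mann-Whitney tests,
    Cohen's d and r effect sizes, chi-square / Fisher tests, Pearson /
    Spearman correlation, Bonferroni adjustment) used for cohort
    comparisons.  Includes a minimal NIfTI-1 reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
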