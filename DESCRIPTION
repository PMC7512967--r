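Package: rrsampen
Title: Sample Entropy and Time-Domain Analysis of RR-Interval Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying heart-rate irregularity from RR-interval
    (inter-beat) series: reading and writing RR recordings, screening for
    ectopic beats and motion artifacts with a relative-jump rule, time-domain
    heart-rate-variability indexes (av-RR, SDNN), Sample Entropy with the
    tolerance expressed as a fraction of the analyzed segment's SDNN
    (default m = 2, r = 0.5 x SDNN), Approximate Entropy for cross-metric
    comparisons, fixed-duration and beat-count sliding-window segmentation,
    seedable synthetic RR generators (AR(1), MIX(p), respiratory sinus
    arrhythmia, artifact injection, calibrated two-condition and time-course
    experiment designs), and a normality-gated nonparametric comparison
    workflow (Wilcoxon, Mann-Whitney, Friedman, Spearman).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
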