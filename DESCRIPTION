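Package: catrace
Title: Quantification and Simulation of GCaMP6s Calcium Transients from
    Line-Scan Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to quantify electrically evoked GCaMP6s calcium
    transients recorded as two-photon line scans from dorsal root ganglion
    neurons, and to forward-simulate such recordings from a
    single-compartment calcium model with SERCA/PMCA clearance and
    first-order indicator binding. Converts raw pixel-by-time line-scan
    matrices into averaged, zero-phase filtered dF/F traces; fits the
    rising phase with a polynomial and the decay with a bi-exponential;
    extracts resting fluorescence, peak amplitude, rise time, decay
    constant (DT1) and residual recovery time (DT2); and provides the
    population statistics used on such tables (simple linear regressions,
    Hartigan's dip test of unimodality with Monte-Carlo p-values,
    Freedman-Diaconis binning, Holm step-down multiple-comparison
    correction, paired t tests). A synthetic population generator with
    known ground truth drives parameter-recovery and pharmacology tests
    (thapsigargin block of SERCA, pH 8.8 block of PMCA, bath-calcium and
    stimulus manipulations).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
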