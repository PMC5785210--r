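Package: epislice
Title: Seizure-Like Event Detection and Patch-Clamp Excitability Analysis
    for Brain Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for epileptiform activity and intrinsic
    excitability in entorhinal-hippocampal brain slices. Detects and
    quantifies seizure-like events (SLEs) in GCaMP calcium-imaging traces
    (delta F/F computation, baseline-drift correction by rolling-percentile
    subtraction, SNR-scaled thresholding, time-in-event binning and plateau
    summaries), analyses voltage-clamp ramp protocols (slope conductance,
    input resistance, normalized washdown time courses of K-ATP-like
    conductance) and current-clamp step protocols (action-potential counting,
    F-I curves), and provides the group-statistics layer (mean +/- SEM,
    boxplot summaries, Student's t test, one-way ANOVA with Bonferroni post
    hoc). A synthetic-data generator with exact ground truth (calcium traces
    with drift, bleach and SLE bursts; passive-membrane ramp recordings with
    time-varying conductance; leaky integrate-and-fire current-clamp sweeps)
    makes every stage testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
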