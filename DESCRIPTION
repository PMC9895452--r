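Package: marmoephys
Title: Extracellular Preprocessing, Spike Curation and Detection-Task
    Psychophysics for Multi-Area Marmoset Recordings
Version: 0.1.0
Authors@R:
    person("ESI", "Analysis", email = "dev@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for semi-chronic multi-shank extracellular
    recordings combined with optogenetic stimulation in behaving marmosets.
    Covers per-shank common-median re-referencing, spike-band filtering
    (Butterworth and high-order Chebyshev type II cascades), multi-unit
    activity (MUA) envelope extraction at 1 kHz, modulation statistics
    (z-score plus Kolmogorov-Smirnov / rank-sum criteria), peristimulus time
    histograms and autocorrelograms, curation of spike-sorted clusters
    (refractory violations, template correlation, spatial spread),
    receptive-field mapping from wedge/annulus stimuli, saccade detection
    from 1 kHz eye traces, detection-task outcome scoring with a
    resampling-based correction for unequal-duration catch trials, pairwise
    chi-squared tests with Benjamini-Hochberg adjustment, and signal
    detection theory (d-prime, criterion) with bootstrap inference. A
    synthetic-data module generates every input with known ground truth so
    the full pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
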