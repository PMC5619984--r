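Package: fastsort
Title: Drift-Tracking Spike Sorting for Long-Term Tetrode Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised spike sorting for continuous, multi-day tetrode
    recordings in which spike waveforms drift slowly over time. Raw voltage
    traces are band-pass filtered, common-median referenced and snippeted;
    snippets are compressed roughly 100-fold into de-noised centroid waveforms
    by blockwise superparamagnetic clustering with a loss-compression tree
    collapse, iterated over four temporal scales; centroids are then linked
    through time into single-unit chains by solving overlapping binary linear
    programs (segmentation fusion). The package also ships a synthetic
    recording generator with per-unit ground truth (geometric random-walk
    amplitude drift, signal-dependent waveform noise, multi-unit background),
    ground-truth validation including the best ellipsoidal error rate (BEER)
    baseline, and cluster-quality, cell-type, correlogram and long-term
    stability metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    e1071,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
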