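Package: migroup
Title: Multi-Subject Time-Frequency Dynamics of Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models common (multi-subject) brain neural dynamics in two-class
    motor-imagery EEG. Subject-level time-frequency feature dynamics are
    extracted by three methods: sliding-window filter-bank Common Spatial
    Patterns (Rayleigh-quotient spatial filters and pattern dynamics),
    dynamic functional connectivity via the trial-ensemble weighted Phase
    Lag Index on Morlet wavelet coefficients, and event-related
    de/synchronization maps with bootstrap significance. Channel relevance
    is assessed per subject by a nonparametric Mann-Whitney thresholding
    rule, corrected across subjects by the positive False Discovery Rate,
    and aggregated into group-level dynamics. Includes BCI-literacy
    clustering of subjects, Gaussian-kernel similarity of group models
    under subject desegregation, a synthetic labeled-cohort generator with
    planted ground truth, a minimal GDF reader, and a pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
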