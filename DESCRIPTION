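Package: seroclass
Title: Serum ESI-MS Peak Profiling and LOOCV/PCV Classification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Implements an electrospray-ionization mass-spectrometry (ESI-MS)
    serum profiling platform for binary clinical group discrimination.
    Raw or tabulated spectra are collapsed to unit-mass bins, locally
    normalized in 25-m/z segments, centroided valley-to-valley, and
    replicate-averaged into per-sample peak-area vectors.  A
    leave-one-out cross-validation (LOOCV) classifier selects
    group-discriminating peaks by one-tailed Welch t-tests and scores
    each held-out sample by a midpoint peak-classification-valuation
    (PCV) threshold at every selected peak.  Distribution-level test
    metrics (Welch t, Cohen's d, noncentral-t power, multiplier cut-off
    lines, confusion counts), a demographically balanced label
    randomization control, blinded and external-cohort assignment, and
    a tandem-MS hit-table fold-change filter with phenotype tallies
    complete the platform.  A seeded synthetic-cohort generator with
    planted differential peaks supports calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mzR,
    optparse
Config/testthat/edition: 3
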