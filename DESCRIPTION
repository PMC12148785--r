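Package: planqc
Title: Automatic Evaluation of External-Beam Breast Radiotherapy Plans
Version: 0.1.0
Authors@R: person("planqc", "authors", role = c("aut", "cre"),
    email = "physics@example.org")
Description: Vendor-independent evaluation engine for external-beam breast
    radiotherapy treatment plans. Reads DICOM-RT dose/structure/plan triplets
    (or tabular cumulative-DVH exports), computes dose-volume histograms and
    dose metrics, checks them against hypofractionated breast protocol
    dose-constraint tables with traffic-light statuses and a protocol
    fulfilment score, maintains a CSV community plan library with similarity
    filtering and percentile (community) scoring, performs plan sanity checks
    (isocenters, monitor units, dose rate, jaws, couch), and provides
    chronological change-detection statistics (squared-deviation series and
    one-tailed Mann-Whitney-Wilcoxon tests). Includes a synthetic box-phantom
    generator with analytically known DVH metrics so the full pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
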