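Package: ojipcap
Title: JIP-Test Analysis of OJIP Chlorophyll Fluorescence Transients with
    Rank-Based Group Statistics and CAP Ordination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives the full JIP-test parameter set (performance index
    PI_ABS, quantum yields, energy fluxes per excited cross-section,
    complementary area) from raw OJIP chlorophyll-a fluorescence induction
    transients, compares parameters across factorial sample groups with
    pairwise Wilcoxon rank-sum tests under Benjamini-Hochberg false
    discovery rate control, and classifies samples by Canonical Analysis of
    Principal Coordinates (CAP) on Euclidean distances with leave-one-out
    allocation and a permutation test. Includes a seeded synthetic OJIP
    transient generator with closed-form ground truth so the whole pipeline
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    pracma,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
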