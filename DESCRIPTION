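Package: ratext
Title: Quantifying Diagnostic Information Hidden in Primary-Care Free Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for estimating how much diagnostic
    information around a first coded rheumatoid-arthritis (RA) diagnosis is
    held only in the free text of primary-care electronic health records.
    Builds an incident-RA cohort from flat-file GPRD/CPRD-style extracts,
    flags indicator Read-code groups and case-insensitive keyword hits in
    free text, analyses the timing of markers relative to the index
    diagnosis, cross-tabulates coded against textual evidence, and counts
    marker combinations usable for probabilistic case definition. Includes
    a calibrated synthetic-record generator so the whole pipeline is
    testable without access to confidential patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
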