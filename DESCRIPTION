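Package: odminsight
Title: Validation, Completeness and Descriptive Statistics for CDISC ODM Study Data
Version: 0.1.0
Authors@R:
    person("ODM Insight", "Developers", email = "odminsight@example.org",
           role = c("aut", "cre"))
Description: Reads CDISC ODM 1.3.x study exports and produces an automatic
    data-quality report: structural validation of the XML against the
    supported ODM grammar, semantic validation of every clinical value
    (reference resolution, data-type conversion, code-list membership),
    per-element reference and subject counts, scale-of-measurement
    descriptive statistics with chart data for every item, and two
    hierarchical completeness measures (mandatory-flag based and
    all-mandatory). Includes a deterministic synthetic-fixture generator
    with ground-truth manifests, a structured JSON report, an invalid-value
    CSV export, an HTML report renderer and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
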