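Package: massql
Title: A Query Language and Engine for Mass Spectrometry Data Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Parse and evaluate pattern queries over mass spectrometry data.
    Queries expressed in a small domain-specific language select MS1 and MS/MS
    scans by diagnostic product ions, neutral losses, precursor constraints,
    variable-anchored isotope and adduct patterns with relative-intensity
    tolerances, and scan metadata (retention time, polarity, charge, scan
    number, ion mobility). Includes readers for mzML, mzXML and MGF, a
    columnar peak-table cache, result and spectrum exporters (TSV, JSON, MGF,
    mzML), a ground-truth synthetic spectra generator for validation, and a
    deterministic multi-file batch runner with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    methods,
    mzR,
    optparse,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
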