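Package: hazmix
Title: Additive Hazard Index Screening for Occupational Chemical Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening-level risk assessment of workplace co-exposure to
    multiple chemicals. Substances are grouped into 24 toxicological classes
    by target organ or mode of action; for each class shared by members of a
    mixture, an additive Hazard Index (the sum of concentration-to-exposure-
    limit ratios, in percent) is computed and situations above 100% are
    flagged. Non-additive "alert" classes (carcinogenicity and/or
    mutagenicity, sensitization, reproductive and developmental toxicity,
    endocrine disruption) trigger warnings instead of an index. Includes a
    substance/occupational-exposure-limit database model with JSON and CSV
    readers and writers, CAS registry number validation, ppm/mg per cubic
    metre conversion, a qualitative shared-class mode for scenarios without
    measurements, ranked machine- and human-readable reports, a command-line
    interface, and generators for synthetic databases and exposure scenarios.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
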