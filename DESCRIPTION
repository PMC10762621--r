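Package: tglisten
Title: Social Media Listening Pipeline for Hypertriglyceridemia Consultations
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable infoveillance pipeline for rule-based analysis
    of online hypertriglyceridemia consultation corpora: Boolean keyword
    retrieval strategies over normalized text, exclusion filtering (duplicate
    IDs, advertisements, popular-science posts, non-topic posts), extraction
    of patient attributes and triglyceride lab values, severity banding and
    consultation-demand classification, and descriptive aggregation into
    frequency tables and time series. Includes a synthetic consultation-corpus
    generator with full ground-truth labels so every pipeline stage can be
    validated by attribute-recovery testing without access to scraped
    platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
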