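Package: sharktag
Title: Tag-Recapture Longevity Analysis for Sharks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Longevity analysis of tagged and recaptured sharks. Inverts the
    von Bertalanffy growth function to backtransform fork length at tagging
    into age, adds time-at-liberty to obtain age at recapture, converts
    vertebral band-pair counts to direct age estimates under a winter
    band-deposition schedule, and compares the two ageing routes with a
    paired t-test built from its defining formulas. Includes a mark-recapture
    simulator (individual growth heterogeneity, length-measurement error,
    annual tag shedding and recapture) that generates pipeline-ready tagging
    studies with known truth for recovery experiments, plus CSV ingestion,
    validation, and report rendering for the standard tagging-study tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
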