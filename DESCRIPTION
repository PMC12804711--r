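Package: claimlines
Title: Line-of-Therapy Derivation and Time-to-Event Outcomes from Oncology Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives lines of therapy (LOT) for diffuse large B-cell lymphoma
    from administrative insurance claims: combination windows, advancement on
    new therapy or stem cell transplant, discontinuation/restart gaps, and
    bridging/salvage/maintenance attribution around CAR T and transplant.
    Applies study eligibility rules (diagnosis confirmation, continuous
    enrollment, washout, exclusion code sets), classifies each line into a
    12-category regimen hierarchy, and estimates overall survival, time to
    next treatment or death, and fixed-horizon treatment failure rates with
    Kaplan-Meier methods. Ships a seedable synthetic claims generator with
    known ground truth so every stage is testable without licensed data, and
    descriptive reporting with small-cell masking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    data.table,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
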