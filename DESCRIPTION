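Package: morsaverted
Title: Deaths Averted by Mobile Overdose Response Services
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the number of fatal drug poisonings potentially
    averted by mobile overdose response services (MORS) and virtual
    overdose monitoring services from per-service emergency-response
    counts. Implements the events-times-fatality-rate estimator three
    ways: deterministic ranges at the endpoints of an uncertain
    unwitnessed-overdose fatality rate, an analytic closed form under a
    uniform rate distribution, and Monte Carlo uncertainty propagation
    with equal-tailed credible intervals. Adds derived programme metrics
    (summed and pooled ranges, jurisdiction subsets, non-fatal to fatal
    ratios, societal cost savings), a report builder, and a synthetic
    counterfactual event-log generator with known ground truth for
    validating estimator bias and interval coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
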