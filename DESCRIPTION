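Package: billheat
Title: Appendage Heat-Budget Modelling and Multimodel Inference for Avian Thermography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates body-region surface areas from morphometrics, converts
    thermal-imaging surface temperatures into region-resolved dry heat loss via
    a radiative plus forced-convective biophysical model, compares groups with
    AICc-based multimodel inference over random-intercept mixed models, and
    translates heat-loss differences into evaporative water-savings
    equivalents. A seeded synthetic-data module emulates a step-wise
    temperature-chamber thermography experiment so the full pipeline runs and
    is testable without original recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
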