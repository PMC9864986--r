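Package: dsfusion
Title: Multi-Sensor Evidence Fusion with Dempster-Shafer Theory
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decision-level fusion of multi-sensor evidence with
    Dempster-Shafer theory. Provides frames of discernment, basic
    probability assignments (BPAs), belief functions and Dempster's
    combination rule; conflict measurement via the Jousselme distance;
    fuzziness measurement via the distance from a BPA to the uniform
    (maximum-entropy) reference; an adaptive weight that combines the two
    with an exponential damping term; trust-discount reallocation of BPAs;
    and an end-to-end wearable activity-recognition pipeline (prototype
    fitting, inverse-distance BPA generation, weighting, discounting,
    fusion, decision and kappa evaluation) with a synthetic-data generator
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
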