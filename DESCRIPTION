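Package: bbrsm
Title: Box-Behnken Response-Surface Optimization for Extraction and Assay Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for three-level Box-Behnken experiments as used in natural-product
    extraction optimization: design construction and coded/natural factor conversion,
    computation of assay responses (extraction yield, total polyphenol content,
    enzyme-inhibition and radical-scavenging rates), full second-order response-surface
    regression with lack-of-fit ANOVA from replicated center points, single- and
    multi-response (desirability) optimization over the design region, and
    external-standard chromatographic quantification with system-suitability metrics
    based on relative retention times and relative peak areas. Includes seeded
    generators for synthetic experiments with known ground truth and a bundled
    four-factor extraction study used throughout the documentation and tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
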