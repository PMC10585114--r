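Package: msntools
Title: Morphometric Similarity Networks with Spatial Nulls and Imaging Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-subject morphometric similarity networks (MSNs) from
    regional cortical morphometry, runs covariate-adjusted case-control
    contrasts on regional MS strength with Benjamini-Hochberg FDR control,
    tests spatial correspondence of parcellated cortical maps against
    spin-rotation null models that preserve spatial autocorrelation, and
    relates case-control t-maps to cortical gene-expression maps through
    rank-1 partial least squares with permutation and bootstrap inference.
    Includes a synthetic-cohort generator with planted regional effects and
    planted gene-map associations so the full pipeline can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
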