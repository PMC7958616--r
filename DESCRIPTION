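Package: wabdecomp
Title: Water Association Band Decomposition for Saccharide Amorphous Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for the infrared Water Association Band
    (WAB, ~2000-2500 cm-1) of protein-saccharide amorphous matrices:
    background subtraction (constant plus Gaussian tail from the CH-stretch
    region), area normalization, taxonomy-constrained Gaussian sub-band
    decomposition with parsimonious (BIC) model selection, fractional
    sub-band populations, replicate aggregation, formulation arithmetic
    (sugar/protein and water/sugar ratios), and cross-composition trend
    analysis (two-family profile clustering, population interconversion,
    red/blue peak shifts). Includes a synthetic-spectrum generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
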