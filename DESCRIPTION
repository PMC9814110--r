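Package: sensda
Title: Defined Approaches for Quantitative Skin Sensitization Potency
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives quantitative endpoints from the three internationally
    harmonized nonanimal skin sensitization assays (direct peptide reactivity
    assay, KeratinoSens, and the human cell line activation test), integrates
    them through small feed-forward neural-network defined approaches run as
    random-initialization ensembles to predict murine local lymph node assay
    (LLNA) EC3 values with 95 percent confidence intervals, curates in vivo
    reference EC3 values from LLNA dose-response studies under two aggregation
    approaches, and compares predicted and reference potency (GHS subcategories,
    dose per skin area, NESIL ratios, error metrics). Includes a synthetic-data
    generator with known ground truth so the full pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
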