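Package: mscpotency
Title: Potency Assessment for Mesenchymal Stromal Cell Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative potency assessment for mesenchymal stem/stromal
    cell (MSC) products. Converts CFSE dye-dilution flow-cytometry events
    into generation profiles and proliferation statistics (replication
    index, division index, percent divided), fits four-parameter logistic
    inhibition curves to extract IC50s for T-cell suppression assays,
    validates surrogate potency markers against functional readouts by
    Pearson correlation and linear calibration, and computes a
    quartile-scored, optionally weighted potency matrix that ranks donors
    or manufactured lots across four immunomodulatory factors (IDO1,
    M-CSF, CD63, CCL2). Includes a synthetic-data generator emulating the
    statistical structure of each assay so every stage of the pipeline
    can be verified against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
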