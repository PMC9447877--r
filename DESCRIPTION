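Package: dropscreen
Title: Pooled shRNA Dropout Screen Analysis with Negative-Binomial Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of pooled short-hairpin RNA (shRNA) dropout screens for
    drug-sensitizer discovery. Implements median-of-ratios depth normalization,
    per-hairpin negative-binomial differential-abundance testing with
    method-of-moments dispersion estimation and trend sharing,
    Benjamini-Hochberg false discovery rate control, a two-step gene-level
    hit-selection cascade (treated-versus-untreated criteria with an
    opposite-direction veto, then a treated-versus-t0 depletion filter), and
    cross-cell-line hit intersection. Ships a seeded synthetic pooled-screen
    generator emulating a kinome library with essential and non-essential
    control hairpins, so every step can be validated against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    yaml
Config/testthat/edition: 3
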