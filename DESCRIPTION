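Package: cnh
Title: Copy-Number Heterogeneity from Bulk Segmented Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies intra-tumour heterogeneity from a single segmented
    bulk copy-number profile. Relative segment values are converted to
    candidate absolute copy numbers over a grid of tumour purity and ploidy,
    and the copy-number heterogeneity (CNH) score is the minimal
    width-weighted mean distance of the absolute values to the nearest
    integers. Includes probe-level noise estimation and quality filters, a
    ground-truth tumour-population simulator for validating recovery of the
    input heterogeneity, and direct heterogeneity estimators for single-cell
    karyotypes and multi-region bulk profiles, with a small command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
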