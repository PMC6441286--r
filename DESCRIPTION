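Package: zassoc
Title: Directional Z Association Coefficient for Contingency Tables
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes the directional (asymmetric) Z association coefficient
    for k x n contingency tables, built from error-rate ratios: Z is 0 at
    independence, 1 under maximal (functional) dependency, and coincides with
    Cramer's V on tables with two columns and with the absolute Pearson
    correlation of the binary indicators on 2 x 2 tables. Supports arbitrary
    grouping (collapsing) of row or column categories, per-cell singular
    coefficients obtained by collapsing each (row, column) pair against the
    pooled remainder, and ranked association lists. Includes classical
    reference measures (chi-squared, phi, Cramer's V, binary Pearson) used as
    independent oracles, seeded synthetic table generators with known
    association structure, delimited-text readers and writers, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
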