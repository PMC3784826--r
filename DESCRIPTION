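Package: trioscreen
Title: Two-Step Combination of Family-Based and Case-Control Genetic
    Association Tests with Conditional-Power Screening
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide association studies that comprise both
    unrelated case-control subjects and mother-father-offspring trios.
    Implements the Cochran-Armitage trend test and its stratum-combined
    (Cochran-Mantel-Haenszel style) version for the unrelated subset, the
    generalized family-based association test (FBAT) with a phenotypic
    offset for the trio subset, and statistically independent screening
    of markers: conditional-power screening from parental genotypes and
    offspring phenotypes for trios, and contingency-table data
    partitioning (C2BAT style) for cases and controls.  Screening
    ranks from the two subsets are aggregated on the log scale and the
    top-K markers are tested with Fisher's combined probability at a
    reduced multiple-testing penalty.  Includes PLINK-style PED/MAP text
    input and output, trio assembly and Mendelian-error quality control,
    a synthetic cohort generator with Mendelian transmission, a logistic
    disease model and optional population stratification, and a single
    pipeline entry point reproducing the full analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
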