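Package: dnaccounting
Title: DNA Accounting for Adulteration Screening of Single-Species
    Biomaterials by Droplet Digital PCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens single-species biomaterials (such as saffron) for
    adulteration with undeclared bulking agents by comparing the number of
    species-specific target copies measured by droplet digital PCR (ddPCR)
    against the number forecast from the sample's DNA template mass and the
    species' genome parameters (monoploid genome weight, ploidy, target copy
    number). Provides Poisson estimation of copies per partition from droplet
    counts, a weighted-least-squares calibration curve with prediction
    intervals for pure reference material, a percent-purity statistic with a
    suspicious/non-suspicious classification band, a simplified copies-per-ng
    population screening rule, and a synthetic-data generator emulating
    droplet partitioning, fluorometric quantification noise, and admixture
    with differential DNA extractability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
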