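Package: sdsreg
Title: Heritability Estimation by Binned Symmetric-Differences-Squared Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Moment-based estimation of additive genetic variance and
    narrow-sense heritability from genome-wide marker data by regressing
    pairwise phenotypic similarity (or half-squared phenotypic differences)
    on pairwise genomic relatedness, using equal-width binning of the
    relatedness range so that the least-squares fit scales to arbitrarily
    large samples. Includes construction of VanRaden-type genomic
    relationship matrices from diploid or haploid marker codes, GCTA binary
    GRM interchange, a single-kernel restricted-maximum-likelihood baseline
    fitted by spectral decomposition, delete-duplicate bootstrap confidence
    intervals, and a first-order autoregressive population simulator for
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
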