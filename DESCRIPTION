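Package: xhweqc
Title: Hardy-Weinberg Equilibrium Tests for X-Chromosome Marker Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-control tests for biallelic X-chromosome markers using
    genotyped founders. Tests the equality of allele frequencies between males
    and females and the absence of excess homozygosity (zero inbreeding
    coefficient) in females, separately and jointly, with moment-based
    chi-square statistics and likelihood-ratio statistics fitted by an EM
    algorithm. Conservative likelihood-ratio tests caused by the boundary null
    (rho = 0) can be calibrated by a parametric bootstrap. Includes a
    Monte-Carlo engine for size/power studies (including a two-subpopulation
    stratification model exhibiting the Wahlund effect), a linkage/PED reader
    that extracts genotyped founders, and per-locus batch analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
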