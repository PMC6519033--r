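Package: rhomap
Title: Variable Population Recombination Rate Estimation from Haplotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates piecewise-constant population recombination rate maps
    (rho = 4*Ne*r per base pair) from phased haplotype data. Short segments of
    the sequence are summarised by linkage-disequilibrium-sensitive statistics
    (haplotype counts, Watterson's theta, pairwise diversity, haplotype
    heterozygosity, the neighbour similarity score, maximal chi-squared and
    optionally Tajima's D); an additive cubic-spline regression, trained on
    coalescent simulations with a Box-Cox transformed response and a
    quantile-regression bias correction, converts the statistics into local
    rate estimates; a simultaneous multiscale change-point estimator with
    type-I error control turns the per-segment track into a parsimonious
    recombination map with hotspot calls. Training under a bottleneck-growth
    demography is supported. Coalescent samples are generated through the
    msprime simulator, driven via a bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    mgcv,
    jsonlite,
    Biostrings,
    vcfR
Suggests: testthat (>= 3.0.0), optparse
SystemRequirements: Python (>= 3.10) with the msprime package on the PATH
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
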