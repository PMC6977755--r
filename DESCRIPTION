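Package: beequant
Title: Quantitative Bee Community Metabarcoding with Copy-Number Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for turning pooled-specimen amplicon sequencing of bee
    communities into quantitative abundance estimates. Simulates specimen
    communities and 28S rRNA amplicon reads with known ground truth, processes
    FASTQ reads into taxon-by-sample count tables (expected-error filtering,
    dereplication, 99 percent identity reference assignment), estimates
    per-taxon rRNA copy-number correction factors with a genetic algorithm
    trained on morphologically concordant samples, and reproduces the
    community-level analytics: richness concordance between morphological and
    molecular identification, sample-based rarefaction with Chao2
    extrapolation, and PCA ordination with per-group convex hulls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
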