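Package: selscape
Title: Genome-Wide Efficacy of Selection in Selfing Plant Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for quantifying the efficacy of
    natural selection across a genome from resequencing data of a
    predominantly selfing diploid. Provides genotype- and site-level
    filtering of VCF callsets, codon-degeneracy and genomic-category
    annotation, GC-biased gene conversion mutation classes, GERP-style
    constraint scoring with conserved-segment discovery, site frequency
    spectra and classical diversity and differentiation statistics
    (pi, Watterson's theta, Tajima's D, Fay and Wu's H, weighted FST,
    dXY, RND), inference of the distribution of fitness effects under
    fitted epoch demography with adaptive-substitution rates (alpha,
    omega), standard and asymptotic McDonald-Kreitman tests,
    composite-likelihood-ratio and integrated-haplotype-score sweep
    scans calibrated against a built-in coalescent simulator, and
    block-bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    Matrix,
    vcfR,
    ape,
    Biostrings,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
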