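Package: islandload
Title: Inbreeding, Runs of Homozygosity and Genetic Load in Island-Mainland Population Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative population-genomic analysis of bottlenecked island
    populations against their mainland counterparts. Provides genotype-quality
    masking (allelic balance and depth filters), outgroup-based ancestral
    allele polarisation, calibrated sliding-window detection of runs of
    homozygosity (ROH) with a false-positive-controlled minimum SNP count and
    F_ROH normalised by a synthetic homozygous genome, a recombination-clock
    age classification for ROH, genetic-load quantification via the relative
    abundance of derived alleles across mutational-effect categories, and
    scans for differentially fixed variants between populations. A forward-time
    two-population Wright-Fisher simulator with selected mutation classes,
    outgroup emission and a sequencing-noise model makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
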