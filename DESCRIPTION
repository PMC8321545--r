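Package: sgvscan
Title: Genome Scans for Selective Sweeps and Standing Genetic Variation in
    Adaptive Radiations
Version: 0.1.0
Authors@R:
    person("sgvscan", "developers", email = "sgvscan@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and interpreting species-specific adaptation
    in recently radiated species complexes from multi-sample variant data.
    Implements sliding-window differentiation statistics (nucleotide
    diversity, Weir-Cockerham weighted FST, absolute divergence dXY), calling
    of highly differentiated regions as empirical FST outliers, integrated
    haplotype score (iHS) selection scans on phased haplotypes, and
    classification of divergent alleles as derived from standing genetic
    variation versus new mutation through gene-tree/species-tree discordance
    with bootstrap support.  A forward-time Wright-Fisher simulator of a
    radiating species complex (with hard sweeps and sweeps from ancient
    balanced polymorphisms) provides synthetic data with known truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
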