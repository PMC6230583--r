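Package: breedscan
Title: Selection Signatures, Haplotype Association and Temporal Allele
    Trajectories in Inbred Breeding Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting loci under selection in inbred crop
    breeding panels genotyped with biallelic SNP arrays, and relating them
    to traits. Provides genotype curation (duplicate removal, imputation,
    MAF and informativeness filters), population structure via discriminant
    analysis of principal components, Weir-Cockerham Fst, AMOVA with
    permutation tests, decade-binned gene diversity, three Fst-outlier
    scans (an FDIST-style neutral envelope, a hierarchical island-model
    null, and a Bayesian Dirichlet-multinomial genome scan with
    reversible-jump MCMC), LD/map-based haplotype-locus construction,
    kinship mixed-model haplotype-trait association with FDR control, and
    temporal allele-frequency trajectory analysis (reversal and fixation
    detection). Includes a calibrated synthetic-panel generator with known
    truth labels so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
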