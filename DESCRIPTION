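Package: mixploidy
Title: Mixed-Ploidy Population Genomics: Dosage Genotyping, Coancestry,
    Admixture and Inheritance-Mode Inference
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for heteroploid (mixed diploid-tetraploid) population
    genomic analysis: ploidy calling from replicated flow-cytometry relative
    fluorescence, empirical-Bayes dosage genotyping from allele read counts
    with per-site error rates, ddRAD-style variant filtering and window
    thinning, mixed-ploidy method-of-moments coancestry with principal
    coordinates analysis, dosage-aware admixture estimation with Evanno
    delta-K model selection and threshold-based introgression classification,
    tetrasomic versus disomic inheritance-mode inference from genotype
    frequency spectra, and presence-raster overlap and habitat-change
    accounting. Includes a synthetic-data generator so the full pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
biocViews: PopulationGenetics, SNP, Genetics, Software
RoxygenNote: 7.3.3
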