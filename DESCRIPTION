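Package: glpopgen
Title: Genotype-Likelihood Population Genomics for Low-Coverage Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genomic inference from low-coverage whole-genome
    sequencing, working throughout with genotype likelihoods rather than hard
    genotype calls. Implements a coalescent simulator for multi-population
    demographies (splits, resizes, exponential growth, migration, admixture
    pulses), genotype-likelihood computation with SNP/MAF/missingness
    filtering, site-allele-frequency likelihoods and EM estimation of folded
    1D and 2D site frequency spectra, windowed diversity statistics (pi,
    Watterson's theta, Tajima's D), Hudson Fst and the population branch
    statistic selection scan, F3 admixture statistics with block-jackknife
    standard errors, composite-likelihood demographic inference on the joint
    SFS with parametric bootstrap, and linkage-disequilibrium r2 estimation
    with decay-curve fitting for post hoc model checking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    minpack.lm,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vcfR,
    yaml
Config/testthat/edition: 3
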