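Package: phyloConv
Title: Recurrent Genotype-Phenotype Association Tests on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects recurrent (convergent) associations between amino acid
    substitutions and a binary phenotype on a phylogeny. Implements marginal
    maximum-likelihood ancestral state reconstruction by Felsenstein pruning,
    three branch-coincidence ("simultaneous") scores for alignment sites
    (Convergence, GWAS, All changes), simulation-based null calibration of
    significance thresholds with familywise error control, a
    foreground/background amino acid profile-change posterior, and a
    synthetic-data generator for birth-death trees, binary traits with a
    controlled number of independent origins, and site-heterogeneous protein
    alignments with planted convergent or profile-change sites.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'phyloConv-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'ancestral.R'
    'io.R'
    'models.R'
    'nullcal.R'
    'pipeline.R'
    'profile.R'
    'scores.R'
    'simulate.R'
    'utils.R'
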