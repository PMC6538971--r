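Package: twopopgen
Title: Two-Population Demographic Inference and Coding Diversity from Genotype Calls
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline from filtered diploid genotype calls to
    population-genomic inference for a pair of populations descended from a
    split. Implements genotype- and site-level variant QC (depth, allele
    balance, genotype quality, GATK-style hard filters), replicate-based
    false-positive SNP window filtering and per-window thinning; per-individual
    heterozygosity, runs of homozygosity via a two-state HMM, KING-robust
    kinship, inbreeding coefficients and genotype PCA; folded one- and
    two-dimensional site frequency spectra with hypergeometric projection and
    the standard diversity statistics (Watterson's theta, pi, Tajima's D,
    piN/piS); composite-likelihood fitting of four two-population demographic
    models (strict isolation, isolation with migration, ancient migration,
    secondary contact) on the folded joint SFS with model comparison by
    likelihood-ratio tests and AIC; estimation of a gamma distribution of
    fitness effects from synonymous and nonsynonymous spectra with a two-epoch
    demographic nuisance; and a comparative life-history layer. A structured
    coalescent simulator with migration epochs, coding site classes and
    sequencing noise makes every stage testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils,
    methods,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
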