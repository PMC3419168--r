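Package: GSeQTL
Title: Gene Set eQTL Association Mapping via PCA Reduction and Wilks' Lambda
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests association between the joint genetic variation and the
    joint mRNA-expression variation of gene sets (pathways). SNPs and
    expression probe sets are mapped to gene sets through their genes, each
    side is reduced by principal component analysis retaining 80% of the
    variance, and the two blocks are related by a multivariate linear model
    assessed with Wilks' lambda. Significance across all cis and trans
    set pairs is calibrated with a permutation-based empirical false
    discovery rate. Includes genotype quality control (call rate, minor
    allele frequency, Hardy-Weinberg equilibrium), mean-dosage imputation,
    expression winsorization, population-stratification eigenvector
    adjustment, a synthetic-data generator with planted effects, and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
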