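Package: transICA
Title: Trans-Acting Regulation of Co-Expression Gene Modules via
    Independent Component Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers co-regulated gene modules in gene-by-sample
    expression matrices by independent component analysis (ICA) and maps
    genomic loci that regulate them in trans. Implements detection and
    gene-name filtering, arcsinh variance stabilization, multidimensional
    scaling outlier detection on expression-correlation and identity-by-
    state distances, permutation-corrected screeplot selection of the
    number of components, multi-restart symmetric FastICA with logcosh
    negentropy, kurtosis and individual-specificity component filters,
    empirical-null local false discovery rate definition of gene modules,
    hypergeometric gene-set enrichment, a two-step SNP-pattern association
    scan (2-df ANOVA then module enrichment at a study-wise threshold),
    cell-type contamination surrogate adjustment, cis-mediation analysis,
    and module-level replication tests. A synthetic-data generator
    produces genotype-driven transcriptomes with known ground truth so
    every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
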