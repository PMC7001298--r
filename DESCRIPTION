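Package: haploNFDS
Title: Negative Frequency-Dependent Selection on Mitochondrial Haplotypes
    from Pool-Seq Experimental Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and quantifying negative frequency-dependent
    selection (NFDS) on a biallelic haplotype system, motivated by the two
    major mitochondrial haplotype groups (HI/HII) segregating in Drosophila
    subobscura. Implements a haploid forward model with a linear
    frequency-dependent fitness map and a 0.5 attractor, the closed-form
    selection-coefficient estimator that inverts it, estimation of haplotype
    frequencies from diagnostic-SNP read counts in pooled (pool-seq) samples,
    and the replicated-line inference layer: split-plot repeated-measures
    ANOVA, permutation tests of between-line effects, percentile bootstrap
    confidence intervals for mean selection coefficients, and a global
    one-sample t-test. A fully seeded synthetic-data generator reproduces the
    statistical structure of a 2 x 2 experimental-evolution design (starting
    frequency x resource environment, replicated lines) with Wright-Fisher
    drift, pooled-fly sampling and per-SNP read counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
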