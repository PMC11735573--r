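Package: tetseg
Title: Tests for Segregation Distortion in Tetraploid F1 Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood ratio and Bayesian tests for segregation distortion at
    biallelic SNPs in F1 populations of tetraploids. The tests are built on a
    gamete-frequency model that jointly accommodates double reduction and
    (partial) preferential pairing, so that well-behaved SNPs in auto-, allo-,
    and segmental allopolyploids are not flagged spuriously. Genotype
    uncertainty is supported through genotype likelihoods, including unknown
    parental genotypes. Also included are the classical chi-squared test and an
    approximation of polymapR's checkF1() segregation test for comparison, a
    simulation harness for null and alternative studies with type-I-error,
    power, and ROC summaries, and readers for VCF and tabular genotype-count
    input.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
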