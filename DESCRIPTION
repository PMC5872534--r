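Package: vgwasim
Title: Simulation of Variance-Heterogeneity Quantitative Trait Loci and
    vGWAS Detection Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates quantitative phenotypes whose mean and residual
    variance both depend on genotype, the signature sought by
    variance-heterogeneity genome-wide association studies (vGWAS).
    Maps per-locus mean and variance effect sizes (fractions of total
    phenotypic variance) and allele frequencies to the parameters of a
    heteroscedastic normal phenotype model, for haploid and diploid
    populations under co-dominance or complete dominance, with any
    number of additive causal loci. Includes a Hardy-Weinberg and
    LD-block genotype generator, readers for ms-style coalescent output
    and VCF, causal-locus selection by allele-frequency criteria, and
    three detectors for validating simulated signals: linear-regression
    association, the Brown-Forsythe variance test, and a double
    generalized linear model testing mean and dispersion jointly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
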