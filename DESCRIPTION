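Package: imprintQG
Title: Quantitative Genetics of a Genomically Imprinted Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: One-locus, two-allele quantitative-genetic model of genomic
    imprinting, where reciprocal heterozygotes differ in mean phenotype.
    Implements five approaches to partitioning breeding values, variance
    components and covariances between relatives; the sex-specific extension
    of the decomposition to an inbred population; and the exact one-generation
    response to selection under a linear fitness function, with its comparison
    to the breeder's equation. Every closed form is cross-validated against an
    exhaustive mating-table enumeration oracle and a seeded Monte Carlo
    population sampler.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
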