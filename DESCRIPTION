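Package: gslchemo
Title: Glucosinolate Chemotype Classification and Evolutionary Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing seed glucosinolate (GSL) profiles of
    Arabidopsis thaliana accessions. From replicated per-compound
    measurements the package estimates broad-sense heritability by ANOVA
    variance partitioning, computes per-accession estimated marginal
    means, runs principal component analysis, and calls the functional
    state of the three major aliphatic GSL loci (MAM/GS-Elong, AOP/GS-AOP
    and GS-OH) to assign each accession one of seven discrete chemotypes.
    Downstream analyses cover north/south environment-association linear
    models, neighbor-joining haplotype trees with bootstrap support and
    clade-to-chemotype concordance, and epistasis-conditioned
    loss-of-function allele frequency analysis. A synthetic-data
    generator with known ground truth makes the whole pipeline testable
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    car,
    emmeans,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
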