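Package: pedscan
Title: Family-Based Linkage and Rare-Variant Prioritization for Multiplex Pedigrees
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genetic analysis of multiplex disease families:
    exact single-family non-parametric linkage analysis (Whittemore-Halpern
    NPL-all scoring over enumerated inheritance vectors, Kong-Cox exponential
    LOD, multipoint hidden Markov chaining, and shore-based linkage-region
    calling), weighted genetic risk scores with the protective-allele
    reciprocal rule, a category-specific rare-variant prioritization cascade
    (frequency, functional-prediction, segregation, linkage-region, and
    external-association filters), kinship-adjusted gene-based burden testing
    across family cohorts, and hypergeometric gene-set over-representation
    analysis. Includes a pedigree genotype simulator (gene dropping with
    map-based recombination and optional disease-locus conditioning) so every
    stage of the pipeline can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
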