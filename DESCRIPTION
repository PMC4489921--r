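Package: cohesim
Title: Cohesin-Dependent Chromosome Domain Architecture from Hi-C, 4C and
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of cohesin/CTCF-dependent chromosome
    organization from binned chromosomal contact data: distance-decay
    expectation and multiplicative bias correction, observed/expected contact
    enrichment, multi-scale contact insulation around binding sites, domain
    border calling and active/passive classification, distance-controlled
    pooling of site-pair submatrices at 2-Kb resolution, wild-type versus
    knockout differential contact maps, 4C-seq profile normalization and
    multi-scale domainograms, and transcriptional-response statistics
    (robust z-scores, binding-site proximity enrichment, same-interval gene
    pair response correlation). Includes a calibrated synthetic-data
    generator producing matched Hi-C, 4C and expression data for wild-type
    and cohesin-depleted conditions, with planted domains, loops, insulating
    sites, technical biases and expression responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
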