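Package: snparent
Title: Unguided SNP-Based Parentage Analysis via Expected-Progeny Gower
    Dissimilarity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers parent-offspring relationships from bi-allelic SNP
    genotype tables without requiring pedigree, gender, or generational
    information. For every candidate parent pair the genotype of their
    expected progeny is constructed from loci homozygous in both parents
    and compared with every potential offspring using the Gower
    dissimilarity; true parent-offspring triads separate from spurious
    associations through a gap in the ordered dissimilarities whose
    significance, and that of each implicated triad, is assessed with
    Dixon outlier tests. When one parent is absent from the population a
    two-stage dyad analysis based on the mean and relative variability of
    expected-progeny dissimilarities (GDM and GDCV normal scores)
    identifies the remaining single parent while discriminating it from
    full siblings. Includes a pedigree simulator with configurable
    genotyping error and missing data for validating the entire pipeline
    against known truth.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
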