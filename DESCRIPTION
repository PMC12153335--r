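Package: mitophylo
Title: Difference-Coded mtDNA Haplotypes, Haplogroup Trees and Classification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curated human mitochondrial DNA phylogenetics: parsing and
    formatting of forensic difference-coded variant notation relative to the revised
    Cambridge Reference Sequence (rCRS), banded global alignment of full mitogenomes
    with 3' phylogenetic placement of indels, haplogroup trees with accumulated full
    signatures, nomenclature-aware subclade integration, cost-based haplogroup
    estimation with private and missing variant reporting, sample-level quality
    control, pathogenic-variant screening and masking with a resolution audit,
    metadata normalization, and a synthetic mitogenome generator for end-to-end
    testing. Includes a command-line interface binding the steps into a pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
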