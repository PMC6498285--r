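Package: sompop
Title: Self-Organizing Map Portrayal of Disease-Associated SNP Genotypes
Version: 0.1.0
Authors@R:
    person("sompop", "developers", email = "sompop@example.org", role = c("aut", "cre"))
Description: Clusters minor-allele-coded SNP genotype profiles on a
    two-dimensional self-organizing map, renders per-individual and
    per-population "SNP portraits", segments minor-allelic spots on the
    population summary map, tests each spot for enrichment of disease
    ontology terms with Fisher's exact test, and relates individuals by a
    minimum spanning tree of portrait correlations. Includes a seeded
    Balding-Nichols simulator of structured multi-population genotype
    panels with planted disease-annotated SNP blocks, an ontology
    level-mapping utility, zoom-in retraining on sample subsets, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    methods,
    jsonlite,
    optparse,
    data.table,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
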