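Package: triometh
Title: Trio-Based Discovery of Candidate Heritable DNA Methylation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies CpG sites whose DNA methylation follows a Mendelian
    inheritance pattern in parent-offspring trios but is not explained by
    genotype, from whole-genome bisulphite sequencing methylation calls.
    Implements methylation-state categorization (unmethylated, intermediate,
    methylated), a diploid epiallele transmission model for trio-compatibility
    testing, the site-filtering cascade (autosomes, SNP overlap, missing data,
    imprinted regions, coverage), an exhaustive cis/trans methylation
    quantitative trait locus scan with Bonferroni control, genomic-context
    annotation (CpG island/shore/shelf/open sea, promoters, chromatin-state
    aggregation), flanking-region scenario classification, hierarchical subject
    clustering, and a seeded synthetic trio-methylome generator with a truth
    set so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: DNAMethylation, Epigenetics, Genetics, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
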