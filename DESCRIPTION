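Package: cazloci
Title: CAZyme Annotation, Polysaccharide Utilization Locus and Cellulosome
    Detection from Binned (Meta)Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-resolved discovery of carbohydrate-active enzymes (CAZymes),
    multimodular enzymes, cellulosome components and polysaccharide utilization
    loci (PULs) from binned genomes or metagenome-assembled genomes. Consumes
    HMMER domtblout-style domain-hit tables, applies dbCAN-style E-value and
    model-coverage filtering, resolves overlapping hits into ordered protein
    domain architectures, calls PULs from tandem susC/susD gene pairs with a
    gene-rank neighborhood window, flags cellulosome-capable genomes from
    cohesin/dockerin co-occurrence, scores sequence novelty as the maximum
    percent identity against a reference protein set, and integrates spectral-
    count metaproteome tables. Includes a synthetic-genome generator that plants
    loci, architectures and identities with a machine-readable truth manifest so
    the whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    graphics,
    utils,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
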