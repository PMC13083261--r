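Package: reefMAGs
Title: Quality Scoring, Species Clustering and Biosynthetic Potential of
    Reef Microbiome Genome Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of metagenome-assembled genome (MAG)
    collections from reef invertebrate microbiomes. Merges dual
    completeness/contamination assessments, applies retention and quality
    tier rules, clusters genomes into species at 95% average nucleotide
    identity with representative selection, quantifies genomic novelty and
    host specificity, analyses community composition (Jaccard distances,
    principal coordinates, PERMANOVA with balanced subsampling, seawater
    distance-decay), computes gene abundances by unique-then-fractional
    insert counting, groups biosynthetic gene clusters into families,
    normalizes biosynthetic richness by sampling effort with rarefaction,
    and scores candidate BGC-rich super-producer species by a composite
    index. Includes a seeded synthetic-data generator with planted species,
    community and gene cluster family structure so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
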