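Package: postgwas
Title: Post-GWAS Functional Annotation, Risk-Locus Characterization and
    Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Offline, scriptable post-GWAS annotation.  Converts GWAS summary
    statistics plus user-supplied reference tables (pairwise LD, gene models,
    variant deleteriousness and regulatory scores, cis-eQTLs, Hi-C chromatin
    interactions, tissue expression, gene-set collections) into characterized
    genomic risk loci, functionally annotated candidate SNPs, genes
    prioritized by positional, eQTL and chromatin-interaction mapping, and
    tissue/pathway enrichment results.  Includes a seeded synthetic-fixture
    generator with planted structure so every stage is testable without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    rtracklayer,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
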