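Package: benthoscan
Title: Comparative Genomics of Gene-Family Expansion, Pan-Genomes and
    Selection in Diatoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects species-specific gene-family expansions from
    copy-number profiles (leave-one-out Z-scores), classifies duplicated
    genes as tandem, block (segmental) or dispersed from gene order and
    family membership, calls per-strain gene presence/absence from exon
    read coverage and partitions a pan-genome into core, softcore and
    dispensable fractions with accumulation curves, estimates per-gene
    nucleotide diversity at nonsynonymous and synonymous sites (piN, piS)
    from annotated coding variants with allele-frequency correction,
    scores clade-specific homology signatures (pennate/centric,
    raphid/araphid, benthic/planktonic), and performs hypergeometric
    gene-family enrichment with pleiotropy and expression-divergence
    classification. A seeded synthetic-data module generates every input
    with planted ground truth so all stages are testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
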