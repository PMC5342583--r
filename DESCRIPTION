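Package: pseudoexonr
Title: Discovery and Evidence Assessment of Deep-Intronic Pseudoexon Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for identifying pseudoexons activated by deep-intronic
    single-nucleotide variants and for weighing the evidence that they are
    pathogenic. Provides HGVS-style cDNA/RNA/protein coordinate arithmetic with
    intronic-offset notation, position-weight scoring of splice donor and
    acceptor sites from the canonical consensus, prediction of pseudoexon
    boundaries from donor-gain variants, splice-junction evidence ingestion
    (STAR SJ tables, BED6) with paired novel-junction detection, allele-specific
    expression analysis (SNuPE allelic ratios and a gene-level binomial
    allelic-imbalance test with Benjamini-Hochberg q-values), WGS-style variant
    filtering (depth, genotype quality, population frequency, inheritance mode),
    pedigree co-segregation checks, and an evidence-tier aggregator. Seeded
    generators produce complete synthetic study cohorts (gene models, genomes,
    variants, junction tables, allelic counts, pedigrees) with ground-truth
    records for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
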