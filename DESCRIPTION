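Package: asrnascreen
Title: Strand-Aware Discovery and Screening of Bacterial cis-Antisense RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An in-silico workflow for discovering cis-antisense small RNAs
    (asRNAs) in bacterial genomes, motivated by antisense regulation in
    Streptomyces coelicolor. Classifies small-RNA genes relative to candidate
    target mRNAs by strand-aware interval geometry (5'-overlapping cis-asRNA,
    3'-end cutoRNA, ambiguous-strand neighbors), runs a candidate funnel that
    combines differential expression in an RNase III (rnc) deletion mutant
    with RNase III co-immunoprecipitation (BARD) binding evidence, designs
    RACE primers and northern probes covering the ribosome binding site and
    start codon, predicts RT-PCR amplicons for operon tests, scans the genome
    for near-identical trans-acting target sites, and normalizes northern
    blot band intensities to the 5S rRNA loading control with classification
    of each transcript's response to RNase III loss. A seeded synthetic-data
    generator plants loci of every orientation category, expression tables
    and band-intensity tables with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
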