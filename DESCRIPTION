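Package: mitocms
Title: Comparative Mitogenome Screening for Cytoplasmic Male Sterility Candidate Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Screens pairs of plant mitochondrial genomes (a cytoplasmic
    male sterility line against its isonuclear maintainer) for candidate
    sterility genes. Calls open reading frames in all six frames of a
    circular genome with plant-mitochondrial start codons, classifies them
    as line-specific (AS), transmembrane (TM, via a Kyte-Doolittle
    hydropathy scan) and chimeric (CH, proximity to conserved protein-coding
    genes on the circle), predicts co-transcription amplicons in silico,
    computes genome composition summaries and 2^-ddCt relative expression,
    and ships a seedable synthetic mitogenome-pair generator with a planted
    truth table so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
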