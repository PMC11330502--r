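Package: subgenomics
Title: Subgenome Phasing, Ks Dating and Polyploid Genome Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics statistics for allopolyploid genomes:
    subgenome phasing from subgenome-specific k-mers, syntelog detection and
    Nei-Gojobori (NG86) Ks estimation with calibration-based divergence
    dating, fractionation-bias analysis, tandem-duplication detection with
    Fisher-exact term enrichment, B-chromosome copy-number estimation and
    origin tracing, minor-allele-frequency ploidy inference, and piN/piS
    deleterious-load estimation. Includes a synthetic allopolyploid genome
    generator with recorded ground truth so every estimator can be exercised
    and validated end-to-end without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
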