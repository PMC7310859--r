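Package: polyhap
Title: Polyploid Haplotype Reconstruction from Short-Read Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Read-based haplotype reconstruction for polyploid genomes.
    Aligned short reads and called variants are reduced to fragments in
    coded allele space; fragments are clustered by mask/seed-sequence
    patterns, clusters are merged into haplotype segments and blocks, and
    blocks are elongated through flanking fragments and a weighted
    k-partite segment graph. Includes a coded-allele-space polyploid
    simulator, plain-text fragment and haplotype formats, and evaluation
    metrics (reconstruction-rate accuracy, haplotype and gap lengths,
    match-mismatch statistics).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    Rsamtools,
    vcfR,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
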