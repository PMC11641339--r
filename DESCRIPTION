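Package: ignarkit
Title: Characterization of Shark IgNAR Loci, Isoforms and VNAR Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing immunoglobulin new antigen receptor (IgNAR)
    genes of cartilaginous fish from genomic and transcriptomic evidence: translated
    (six-frame) local-alignment search for IgNAR-like loci on assembly scaffolds,
    resolution of assembly N-gaps by overlap-consensus extension of locally mapped
    read pairs, reconstruction of splice isoforms and their constant-domain
    architecture from spliced alignments, positional annotation of VNAR single
    domains with cysteine-pattern type classification and predicted disulfide
    bonds, geometric verification of disulfide bonds on predicted structures, and
    a synthetic-data generator that emulates IgNAR-like loci, gapped scaffolds,
    sequencing reads and VNAR repertoires so the whole workflow is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
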