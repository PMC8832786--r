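Package: nlrkit
Title: Annotation and Comparative Analysis of NLR Resistance Gene Repertoires
    from Enrichment-Sequencing Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for cataloguing nucleotide-binding leucine-rich-repeat (NLR)
    immune receptor genes from long-read resistance-gene enrichment sequencing
    (SMRT-RenSeq) assemblies. Provides contig de-redundancy with rescue rules for
    removed contigs, low-complexity masking, six-frame motif scanning and chaining
    of motif hits into NLR loci with completeness and pseudogene calls,
    homology-guided protein prediction, merging of domain annotations and Type
    I-V classification including integrated-domain (NLR-ID) detection,
    neighbor-joining phylogenies of NB-ARC domains with bootstrap support,
    homoeologous chromosome-group assignment with congruence reports against
    physical translocation-line data, orthologue and expression screens, private
    indel marker discovery, and cross-species integrated-domain comparison. A
    synthetic-data generator plants motif-grammar NLR loci with known ground
    truth so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
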