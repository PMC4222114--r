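Package: vitisnp
Title: Character-Based SNP Genotyping for Cultivar Identity in Clonal Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single-copy nuclear-gene SNP genotyping of diploid, clonally
    propagated cultivars from Sanger consensus alignments in which
    heterozygous positions are recorded as IUPAC ambiguity codes. Provides
    polymorphic-site discovery with indel and ambiguity screening,
    concatenated multi-marker genotype reconstruction and collapsing into
    genotype groups, diagnostic characteristic-attribute (CA) keys
    (pure-simple and minimal compound), synonymy/homonymy/mislabel
    detection, Kimura two-parameter distances with ambiguity-aware pairwise
    deletion, neighbor-joining trees with bootstrap supports, per-subgroup
    diversity statistics (na, ne, Shannon I, Nei H, Ho, He, Fis), a
    ground-truthed synthetic data generator, and an end-to-end pipeline
    with a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
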