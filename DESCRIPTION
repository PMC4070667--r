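Package: otnsa
Title: Alignment-Free 16S rRNA Amplicon Analysis with Orthologous Tri-Nucleotides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo semi-alignment of 16S rRNA amplicon reads based on
    Orthologous Tri-Nucleotides (OTNs): positional trinucleotide histograms,
    peak detection and binning, binary presence/absence OTN matrices with a
    homopolymer multiplicity-discharge rule, exponential-decay generation
    distances, neighbor-joining phylogenies with column bootstrap support,
    and OTN-pattern alpha/beta diversity and PCA ordination. Includes read
    quality trimming, primer stripping, depth normalization, and a synthetic
    amplicon simulator with known evolutionary and homopolymer error
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
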