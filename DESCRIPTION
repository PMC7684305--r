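Package: sedaforam
Title: Sedimentary eDNA Metabarcoding of Planktonic Foraminifera
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse sedimentary environmental DNA
    (sedaDNA) metabarcoding studies of foraminifera. Provides a synthetic
    sediment-core study generator (taxonomy-annotated reference barcodes,
    depth- and zone-structured communities, tagged paired-end reads, coupled
    microfossil census counts), the bespoke amplicon-processing chain used for
    the foraminiferal 37f SSU marker (quality filtering, exact-overlap pair
    merging, tagged-primer demultiplexing, chimera removal, dereplication to
    ISUs, Needleman-Wunsch taxonomic assignment, prefix pre-clustering and
    average-linkage OTU delineation), a planktonic/benthic DNA burial-decay
    model with least-squares parameter fitting, and community-comparison
    statistics (cumulative sum scaling, Bray-Curtis, principal coordinates,
    dispersion and permutation ANOVA tests, Mantel congruence).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    vegan,
    yaml,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
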