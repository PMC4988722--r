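Package: tdarec
Title: Topological Detection and Quantification of Recombination in Binary Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects, counts, locates and scales recombination events in a
    sample of binary haplotypes using persistent homology. Builds
    Vietoris-Rips filtrations over Hamming distances, computes
    first-persistent-homology barcodes over GF(2), and combines interval
    barcodes over optimally chosen partitions of segregating sites into a
    barcode ensemble whose bar count lower-bounds the number of recombination
    events. Also provides the classical haplotype, Hudson-Kaplan and
    Myers-Griffiths lower bounds on the minimum number of recombinations, an
    exact minimum-recombination oracle for tiny instances with ultra-minimal
    history reconstruction, partial reconstruction of topological ancestral
    recombination graphs from homology generators, and a Hudson-style
    coalescent simulator with recombination, population structure and
    migration for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
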