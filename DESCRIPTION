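Package: helitronr
Title: Discovery and Structural Characterization of Helitron Transposons
Version: 0.1.0
Authors@R:
    person("helitronr", "maintainers", email = "helitronr@example.org",
           role = c("aut", "cre"))
Description: Tools to discover and characterize helitron rolling-circle DNA
    transposons in genomic sequence. Scans genomes for the family-specific
    helA/helB terminal motifs at loose and strict stringency, pairs 5'- and
    3'-terminus hits into intact element calls under a 20 kb span rule,
    annotates AT insertion-site flanks, sub-terminal hairpins and putative
    autonomy, classifies real versus pseudo (decayed CTAT) 3'-termini,
    profiles multiple-termini elements and predicts the products of nested
    transpositions, performs seed-and-extend local similarity search for
    homology-based discovery, boundary validation and tiered copy-number
    counting, decomposes related elements into shared segment blocks to
    infer stepwise gene-fragment capture and internal-loss histories, and
    simulates genomes with planted elements and full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
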