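Package: MotifContrast
Title: Difference Logos and Comparative Visualization of Sequence Motifs
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pairwise and multi-motif comparison of sequence motifs over DNA,
    RNA, protein or user-defined alphabets. Per-position differences between
    two position weight matrices are summarized as a difference logo: the
    stack height at each position is the Jensen-Shannon divergence (in bits)
    between the two symbol distributions, and the signed letter heights are
    normalized probability differences, so symbols losing abundance in the
    second motif point upward and symbols gaining abundance point downward.
    Summing stack heights yields a scalar motif dissimilarity that drives
    hierarchical clustering with optimal leaf ordering and an N-by-N grid of
    difference logos with a green-to-red background gradient. Includes readers
    and writers for JASPAR-style and tabular matrices, aligned FASTA input,
    distance-matrix TSV and Newick export, deterministic SVG/PDF/PNG
    rendering with built-in polygon glyphs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, grDevices, graphics, tools, Biostrings
Suggests: testthat (>= 3.0.0), ape, xml2, jsonlite, withr
biocViews: MotifAnnotation, SequenceMatching, Visualization, Alignment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
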