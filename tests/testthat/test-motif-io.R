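test_that("readJaspar parses bracketed and bare rows identically", {
    txt <- ">M1\nA [ 2 0 ]\nC [ 0 2 ]\nG [ 0 0 ]\nT [ 0 0 ]"
    m <- readJaspar(text = txt)[[1]]
    expect_s4_class(m, "CountMotif")
    expect_equal(motifLabel(m), "M1")
    expect_equal(motifLength(m), 2L)
    expect_equal(unname(counts(m)[1, ]), c(2, 0, 0, 0))
    bare <- ">M1\nA 2 0\nC 0 2\nG 0 0\nT 0 0"
    expect_equal(counts(readJaspar(text = bare)[[1]]), counts(m))
    # symbol rows in arbitrary order
    shuf <- ">M1\nT 0 0\nA 2 0\nG 0 0\nC 0 2"
    expect_equal(counts(readJaspar(text = shuf)[[1]]), counts(m))
})

test_that("readJaspar rejects malformed records and infers alphabets", {
    expect_error(readJaspar(text = ">M\nA 1 2\nC 1\nG 1 2\nT 1 2"),
                 "ragged")
    expect_error(readJaspar(text = ">M\nA 1\nA 2\nG 1\nT 1"),
                 "duplicate")
    u <- readJaspar(text = ">R\nA 1\nC 1\nG 1\nU 1")[[1]]
    expect_identical(alphabet(u)@name, "RNA")
    prot <- paste(c(">P", paste(alphabetSymbols(proteinAlphabet()), "1")),
                  collapse = "\n")
    expect_identical(alphabet(readJaspar(text = prot)[[1]])@name,
                     "protein")
})

test_that("JASPAR write/read round-trips counts and probabilities", {
    set.seed(3)
    m <- sequencesToCounts(vapply(1:20, function(i)
        paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE),
              collapse = ""), ""), "dna", label = "rt")
    f <- withr::local_tempfile(fileext = ".pfm")
    writeJaspar(m, f)
    back <- readJaspar(f)[[1]]
    expect_equal(counts(back), counts(m))
    expect_equal(motifLabel(back), "rt")
    pm <- countsToProbabilities(m, 1)
    writeJaspar(pm, f)
    pback <- readJaspar(f)[[1]]
    expect_s4_class(pback, "ProbabilityMotif")
    expect_equal(probs(pback), probs(pm), tolerance = 1e-6)
})

test_that("readTabularMotif honors orientation and rejects bad shapes", {
    set.seed(4)
    m <- rand_pm(10)
    f1 <- withr::local_tempfile(fileext = ".tsv")
    # symbols x positions, no headers
    writeLines(apply(t(probs(m)), 1, paste, collapse = "\t"), f1)
    r1 <- readTabularMotif(f1, "dna", "symbols_by_positions",
                           "probabilities")
    expect_equal(probs(r1), probs(m), tolerance = 1e-9)
    expect_equal(motifLength(r1), 10L)
    # positions x symbols with header (the writer's format)
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeTabularMotif(m, f2)
    r2 <- readTabularMotif(f2, "dna", "positions_by_symbols",
                           "probabilities")
    expect_equal(probs(r2), probs(m), tolerance = 1e-6)
    # unambiguous orientation is inferred; wrong alphabet errors
    r3 <- readTabularMotif(f2, "dna", kind = "probabilities")
    expect_equal(probs(r3), probs(m), tolerance = 1e-6)
    expect_error(readTabularMotif(f2, "protein", kind = "probabilities"),
                 "shape")
})

test_that("square tabular matrices require an explicit orientation", {
    m <- rand_pm(4)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(apply(probs(m), 1, paste, collapse = "\t"), f)
    expect_error(readTabularMotif(f, "dna", kind = "probabilities"),
                 "ambiguous")
    r <- readTabularMotif(f, "dna", "positions_by_symbols",
                          "probabilities")
    expect_equal(probs(r), probs(m), tolerance = 1e-9)
})

test_that("readFastaMotif tallies alignments and validates lengths", {
    f <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(">a", "ACGT", ">b", "acgt", ">c", "ACGT"), f)
    m <- readFastaMotif(f, "dna")
    expect_equal(unname(rowSums(counts(m))), rep(3, 4))
    expect_equal(unname(counts(m)[1, ]), c(3, 0, 0, 0))
    # mixed case identical to upper case
    f2 <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(">a", "ACGT", ">b", "ACGT", ">c", "ACGT"), f2)
    m2 <- readFastaMotif(f2, "dna")
    expect_equal(sum(counts(m2)[, 1] == 3), 1L)
    # unequal lengths name the offending record
    f3 <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(">a", "ACGT", ">bad", "ACG"), f3)
    expect_error(readFastaMotif(f3, "dna"), "bad")
    f4 <- withr::local_tempfile(fileext = ".fasta")
    writeLines(character(), f4)
    expect_error(readFastaMotif(f4, "dna"))
})

test_that("distance matrix TSV round-trips within 1e-6", {
    d <- new("DissimilarityMatrix",
             values = matrix(c(0, 1.5, 1.5, 0), 2, 2,
                             dimnames = list(c("A", "B"), c("A", "B"))))
    f <- withr::local_tempfile(fileext = ".tsv")
    writeDistanceMatrix(d, f)
    expect_length(readLines(f), 3L)
    expect_equal(dissimilarityValues(readDistanceMatrix(f)),
                 dissimilarityValues(d), tolerance = 1e-6)
    set.seed(5)
    big <- rand_dissim(7)
    writeDistanceMatrix(big, f)
    expect_equal(dissimilarityValues(readDistanceMatrix(f)),
                 dissimilarityValues(big), tolerance = 1e-6)
})

test_that("asymmetric matrices are rejected by the class invariant", {
    v <- matrix(c(0, 1, 2, 0), 2, 2,
                dimnames = list(c("A", "B"), c("A", "B")))
    expect_error(new("DissimilarityMatrix", values = v), "symmetric")
})

test_that("writeNewick emits parseable ultrametric trees", {
    d <- new("DissimilarityMatrix",
             values = matrix(c(0, 1.5, 1.5, 0), 2, 2,
                             dimnames = list(c("A", "B"), c("A", "B"))))
    tree <- clusterMotifs(d)
    f <- withr::local_tempfile(fileext = ".nwk")
    nwk <- writeNewick(tree, f)
    expect_match(nwk, "^\\([AB]:0\\.75,[AB]:0\\.75\\);$")
    ph <- ape::read.tree(f)
    expect_setequal(ph$tip.label, c("A", "B"))
    expect_equal(unname(ph$edge.length), c(0.75, 0.75))
    # random trees: leaf set preserved, ultrametric depths match height/2
    set.seed(6)
    for (i in 1:5) {
        dm <- rand_dissim(sample(3:7, 1))
        tr <- clusterMotifs(dm, "average")
        writeNewick(tr, f)
        ph <- ape::read.tree(f)
        expect_setequal(ph$tip.label, motifLabels(dm))
        depth <- max(ape::node.depth.edgelength(ph))
        expect_equal(depth, max(tr$height) / 2, tolerance = 1e-6)
    }
})

test_that("Newick labels with spaces are quoted", {
    v <- matrix(c(0, 2, 2, 0), 2, 2,
                dimnames = list(c("cell line A", "B"),
                                c("cell line A", "B")))
    d <- new("DissimilarityMatrix", values = v)
    f <- withr::local_tempfile(fileext = ".nwk")
    nwk <- writeNewick(clusterMotifs(d), f)
    expect_match(nwk, "'cell line A'", fixed = TRUE)
})
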