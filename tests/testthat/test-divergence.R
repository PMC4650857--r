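test_that("information content matches closed forms", {
    expect_equal(informationContent(rep(0.25, 4)), 0)
    expect_equal(informationContent(c(1, 0, 0, 0)), 2)
    expect_equal(informationContent(c(0.5, 0.5, 0, 0)), 1)
    expect_equal(informationContent(rep(1 / 20, 20)), 0)
    expect_equal(informationContent(c(1, rep(0, 19))), log2(20))
})

test_that("classic symbol heights are frequencies scaled by conservation", {
    expect_equal(classicSymbolHeights(c(1, 0, 0, 0)), c(2, 0, 0, 0))
    expect_equal(classicSymbolHeights(rep(0.25, 4)), rep(0, 4))
    expect_equal(classicSymbolHeights(c(0.5, 0.5, 0, 0)),
                 c(0.5, 0.5, 0, 0))
    set.seed(21)
    for (i in 1:50) {
        p <- rand_dist(sample(c(4L, 20L), 1))
        h <- classicSymbolHeights(p)
        expect_true(all(h >= 0))
        expect_equal(sum(h), informationContent(p), tolerance = 1e-12)
    }
})

test_that("Jensen-Shannon divergence reproduces the worked single-column cases", {
    expect_equal(jsDivergence(c(1, 0, 0, 0), c(0, 1, 0, 0)), 1)
    expect_equal(jsDivergence(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5)), 1)
    expect_equal(jsDivergence(c(0.5, 0.5, 0, 0), c(0.5, 0, 0.5, 0)), 0.5)
    p <- c(0.8, 0.2, 0, 0); q <- c(0.2, 0.8, 0, 0)
    expect_equal(jsDivergence(p, q), js_oracle(p, q), tolerance = 1e-14)
    expect_equal(jsDivergence(p, p), 0)
    expect_error(jsDivergence(c(1, 0, 0, 0), c(1, 0, 0)), "mismatch")
})

test_that("JSD is symmetric, bounded by [0,1] bits, zero iff equal", {
    set.seed(22)
    for (i in 1:200) {
        k <- sample(c(4L, 20L), 1)
        p <- rand_dist(k); q <- rand_dist(k)
        v <- jsDivergence(p, q)
        expect_gte(v, 0)
        expect_lte(v, 1)
        expect_identical(v, jsDivergence(q, p))
        expect_gt(v, 0)  # random pairs differ a.s.
    }
    # maximum attained only for disjoint supports
    expect_equal(jsDivergence(c(1, rep(0, 19)), c(0, 1, rep(0, 18))), 1)
})

test_that("normalized probability differences satisfy their contract", {
    expect_equal(normalizedProbDifference(c(1, 0, 0, 0), c(0, 1, 0, 0)),
                 c(0.5, -0.5, 0, 0))
    expect_equal(normalizedProbDifference(c(0.3, 0.7, 0, 0),
                                          c(0.3, 0.7, 0, 0)), rep(0, 4))
    expect_equal(normalizedProbDifference(c(0.6, 0.4, 0, 0),
                                          c(0.4, 0.4, 0.2, 0)),
                 c(0.5, 0, -0.5, 0))
    set.seed(23)
    for (i in 1:100) {
        p <- rand_dist(4); q <- rand_dist(4)
        r <- normalizedProbDifference(p, q)
        expect_equal(sum(r), 0, tolerance = 1e-12)
        expect_equal(sum(abs(r)), 1, tolerance = 1e-12)
        expect_equal(r, -normalizedProbDifference(q, p))
    }
})

test_that("difference columns conserve gain and loss", {
    dc <- differenceColumn(c(1, 0, 0, 0), c(0, 1, 0, 0))
    expect_equal(dc$stackHeight, 1)
    expect_equal(dc$symbolHeights, c(0.5, -0.5, 0, 0))
    same <- differenceColumn(c(0.4, 0.6, 0, 0), c(0.4, 0.6, 0, 0))
    expect_equal(same$stackHeight, 0)
    expect_equal(same$symbolHeights, rep(0, 4))
    set.seed(24)
    for (i in 1:200) {
        k <- sample(c(4L, 20L), 1)
        p <- rand_dist(k); q <- rand_dist(k)
        dc <- differenceColumn(p, q)
        expect_equal(sum(dc$symbolHeights), 0, tolerance = 1e-9)
        expect_equal(sum(abs(dc$symbolHeights)), dc$stackHeight,
                     tolerance = 1e-9)
        expect_equal(sum(dc$symbolHeights[dc$symbolHeights > 0]),
                     dc$stackHeight / 2, tolerance = 1e-9)
    }
})

test_that("motif dissimilarity D sums stack heights and is additive", {
    dna <- dnaAlphabet()
    a <- probabilityMotif(rbind(c(1, 0, 0, 0)), dna)
    b <- probabilityMotif(rbind(c(0, 1, 0, 0)), dna)
    expect_equal(motifDissimilarity(a, b), 1)
    expect_equal(motifDissimilarity(a, a), 0)
    # concatenating the 1-bit and 0.5-bit cases gives 1.5 by additivity
    p <- probabilityMotif(rbind(c(1, 0, 0, 0), c(0.5, 0.5, 0, 0)), dna)
    q <- probabilityMotif(rbind(c(0, 1, 0, 0), c(0.5, 0, 0.5, 0)), dna)
    expect_equal(motifDissimilarity(p, q), 1.5)
    expect_error(motifDissimilarity(a, p), "length mismatch")
    # explicit padding equals dissimilarity of the padded motifs
    expect_equal(motifDissimilarity(a, p, pad = TRUE),
                 motifDissimilarity(padMotif(a, 2), p))
    rna <- probabilityMotif(rbind(c(1, 0, 0, 0)), "rna")
    expect_error(motifDissimilarity(a, rna), "alphabet")
})

test_that("the measure registry exposes working alternatives", {
    reg <- listMeasures()
    expect_setequal(reg$stackHeight,
                    c("jensenShannon", "sumAbsProbDiff", "infoContentDiff"))
    expect_setequal(reg$symbolWeight,
                    c("normalizedProbDiff", "rawProbDiff"))
    expect_equal(stackHeightMeasure("sumAbsProbDiff")(c(1, 0, 0, 0),
                                                      c(0, 1, 0, 0)), 2)
    expect_equal(stackHeightMeasure("infoContentDiff")(c(0.3, 0.7, 0, 0),
                                                       c(0.3, 0.7, 0, 0)),
                 0)
    expect_equal(symbolWeightMeasure("rawProbDiff")(c(0.6, 0.4, 0, 0),
                                                    c(0.4, 0.4, 0.2, 0)),
                 c(0.2, 0, -0.2, 0))
    expect_error(stackHeightMeasure("nope"), "jensenShannon")
    expect_error(symbolWeightMeasure("nope"), "normalizedProbDiff")
    # every registered stack height vanishes on identical distributions
    set.seed(25)
    for (nm in reg$stackHeight) {
        f <- stackHeightMeasure(nm)
        for (i in 1:100) {
            p <- rand_dist(4)
            expect_equal(f(p, p), 0, tolerance = 1e-12)
        }
    }
    # every registered symbol weight sums to zero and is antisymmetric
    for (nm in reg$symbolWeight) {
        f <- symbolWeightMeasure(nm)
        for (i in 1:50) {
            p <- rand_dist(4); q <- rand_dist(4)
            expect_equal(sum(f(p, q)), 0, tolerance = 1e-12)
            expect_equal(f(p, q), -f(q, p), tolerance = 1e-15)
        }
    }
})

test_that("custom measure functions plug into measurePair", {
    mp <- measurePair(function(p, q) sum(abs(p - q)) / 2,
                      "normalizedProbDiff")
    a <- probabilityMotif(rbind(c(1, 0, 0, 0)), "dna")
    b <- probabilityMotif(rbind(c(0, 1, 0, 0)), "dna")
    expect_equal(motifDissimilarity(a, b, mp), 1)
    expect_identical(mp@names[1], "custom")
})
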