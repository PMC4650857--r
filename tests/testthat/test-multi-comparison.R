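test_that("pairwise dissimilarity matrix is symmetric with zero diagonal", {
    dna <- dnaAlphabet()
    a <- probabilityMotif(rbind(c(1, 0, 0, 0)), dna, label = "A1")
    b <- probabilityMotif(rbind(c(0, 1, 0, 0)), dna, label = "C1")
    dm <- pairwiseDissimilarity(list(a, b))
    expect_equal(unname(dissimilarityValues(dm)),
                 matrix(c(0, 1, 1, 0), 2, 2))
    dm2 <- pairwiseDissimilarity(list(a, a))
    expect_equal(unname(dissimilarityValues(dm2)), matrix(0, 2, 2))
    set.seed(41)
    ms <- lapply(1:5, function(i) rand_pm(6, label = paste0("m", i)))
    v <- dissimilarityValues(pairwiseDissimilarity(ms))
    expect_identical(v, t(v))
    expect_equal(unname(diag(v)), rep(0, 5))
    for (i in 1:4) for (j in (i + 1):5)
        expect_equal(v[i, j], motifDissimilarity(ms[[i]], ms[[j]]))
    expect_error(pairwiseDissimilarity(list(a)), "at least two")
})

test_that("clustering merges the closest motifs first", {
    labs <- c("A", "B", "C")
    v <- matrix(c(0, 0.1, 1, 0.1, 0, 1, 1, 1, 0), 3, 3,
                dimnames = list(labs, labs))
    dm <- new("DissimilarityMatrix", values = v)
    for (lk in c("complete", "average", "single")) {
        tr <- clusterMotifs(dm, lk)
        expect_equal(sort(tr$labels[-tr$merge[1, ]]), c("A", "B"))
        expect_equal(tr$height[1], 0.1)
    }
    two <- new("DissimilarityMatrix",
               values = matrix(c(0, 2, 2, 0), 2, 2,
                               dimnames = list(c("x", "y"), c("x", "y"))))
    tr <- clusterMotifs(two)
    expect_equal(length(tr$height), 1L)
    expect_equal(tr$height, 2)
})

test_that("complete linkage agrees with a naive agglomeration oracle", {
    naive_heights <- function(d) {
        groups <- as.list(seq_len(nrow(d)))
        hts <- numeric()
        while (length(groups) > 1) {
            best <- Inf; bi <- 0; bj <- 0
            for (i in seq_along(groups)) for (j in seq_along(groups)) {
                if (j <= i) next
                lk <- max(d[groups[[i]], groups[[j]]])
                if (lk < best) { best <- lk; bi <- i; bj <- j }
            }
            hts <- c(hts, best)
            groups[[bi]] <- c(groups[[bi]], groups[[bj]])
            groups[[bj]] <- NULL
        }
        hts
    }
    set.seed(42)
    for (i in 1:10) {
        dm <- rand_dissim(sample(3:6, 1))
        tr <- clusterMotifs(dm, "complete")
        expect_equal(tr$height, naive_heights(dissimilarityValues(dm)),
                     tolerance = 1e-12)
    }
})

test_that("optimal leaf order minimizes the adjacent-pair sum", {
    # N = 2: both orders optimal, lexicographically first returned
    two <- new("DissimilarityMatrix",
               values = matrix(c(0, 1, 1, 0), 2, 2,
                               dimnames = list(c("b", "a"), c("b", "a"))))
    expect_identical(optimalLeafOrder(clusterMotifs(two), two),
                     c("a", "b"))
    # N = 3 star: the close pair must be adjacent
    labs <- c("A", "B", "C")
    v <- matrix(c(0, 0.1, 1, 0.1, 0, 1.2, 1, 1.2, 0), 3, 3,
                dimnames = list(labs, labs))
    v <- (v + t(v)) / 2
    dm <- new("DissimilarityMatrix", values = v)
    ord <- optimalLeafOrder(clusterMotifs(dm), dm)
    expect_equal(abs(match("A", ord) - match("B", ord)), 1L)
    # exhaustive verification over subtree flips for random instances
    set.seed(43)
    for (i in 1:30) {
        dm <- rand_dissim(sample(3:8, 1))
        tr <- clusterMotifs(dm)
        ord <- optimalLeafOrder(tr, dm)
        d <- dissimilarityValues(dm)
        all_orders <- flip_orders(tr)
        best <- min(vapply(all_orders, adjacent_sum, 0, d = d))
        expect_equal(adjacent_sum(ord, d), best, tolerance = 1e-12)
        # the returned order is realizable by flips
        keys <- vapply(all_orders, paste, "", collapse = "|")
        expect_true(paste(ord, collapse = "|") %in% keys)
    }
    bad <- rand_dissim(3)
    expect_error(optimalLeafOrder(clusterMotifs(rand_dissim(4)), bad),
                 "label mismatch")
})

test_that("comparison grid has mirrored cells and endpoint colors", {
    set.seed(44)
    ms <- lapply(1:4, function(i) rand_pm(5, label = paste0("m", i)))
    g <- buildComparisonGrid(ms)
    n <- 4
    syms <- alphabetSymbols(dnaAlphabet())
    v <- dissimilarityValues(g@dissimilarity)[g@ordering, g@ordering]
    off <- v[row(v) != col(v)]
    for (i in 1:n) for (j in 1:n) {
        if (i == j) {
            expect_null(g@cells[[i]][[j]])
            expect_identical(g@cellColors[i, j], "")
            next
        }
        for (l in 1:5)
            expect_equal(
                column_heights(g@cells[[i]][[j]]@columns[[l]], syms),
                -column_heights(g@cells[[j]][[i]]@columns[[l]], syms),
                tolerance = 1e-12)
        # endpoint colors hit exactly at the extreme pairs
        if (v[i, j] == min(off))
            expect_identical(toupper(g@cellColors[i, j]), "#00B000")
        if (v[i, j] == max(off))
            expect_identical(toupper(g@cellColors[i, j]), "#D00000")
    }
    expect_equal(g@sharedOrdinate,
                 commonOrdinate(Filter(Negate(is.null),
                                       unlist(g@cells, recursive = FALSE))))
})

test_that("identical motifs give an all-green grid of empty cells", {
    m <- probabilityMotif(rbind(c(0.7, 0.1, 0.1, 0.1)), "dna")
    ms <- list(a = m, b = m, c = m)
    g <- buildComparisonGrid(ms)
    for (i in 1:3) for (j in 1:3) {
        if (i == j) next
        expect_identical(toupper(g@cellColors[i, j]), "#00B000")
        expect_equal(nrow(g@cells[[i]][[j]]@columns[[1]]), 0L)
    }
})

test_that("clustering and leaf order are permutation-equivariant", {
    set.seed(45)
    ms <- lapply(1:5, function(i) rand_pm(6, label = paste0("m", i)))
    g1 <- buildComparisonGrid(ms)
    perm <- c(4, 2, 5, 1, 3)
    g2 <- buildComparisonGrid(ms[perm])
    expect_identical(g1@ordering, g2@ordering)
    expect_equal(sort(g1@tree$height), sort(g2@tree$height))
    expect_equal(dissimilarityValues(g1@dissimilarity)[g1@ordering,
                                                       g1@ordering],
                 dissimilarityValues(g2@dissimilarity)[g2@ordering,
                                                       g2@ordering])
})

test_that("two clean clusters sit contiguously with near pairs near the diagonal", {
    dna <- dnaAlphabet()
    base1 <- rbind(c(1, 0, 0, 0), c(0.5, 0.5, 0, 0), rep(0.25, 4))
    base2 <- rbind(c(0, 0, 1, 0), c(0, 0, 0.5, 0.5), rep(0.25, 4))
    wiggle <- function(m, eps) {
        m[3, ] <- c(0.25 + eps, 0.25 - eps, 0.25, 0.25)
        m
    }
    ms <- list(
        a1 = probabilityMotif(wiggle(base1, 0.00), dna),
        a2 = probabilityMotif(wiggle(base1, 0.02), dna),
        b1 = probabilityMotif(wiggle(base2, 0.00), dna),
        b2 = probabilityMotif(wiggle(base2, 0.02), dna),
        b3 = probabilityMotif(wiggle(base2, 0.04), dna))
    g <- buildComparisonGrid(ms)
    grp <- substr(g@ordering, 1, 1)
    expect_equal(length(rle(grp)$lengths), 2L)   # clusters contiguous
    # dissimilarity grows with distance from the diagonal, band by band
    v <- dissimilarityValues(g@dissimilarity)[g@ordering, g@ordering]
    bandMean <- vapply(1:4, function(k)
        mean(v[abs(row(v) - col(v)) == k]), 0)
    # within-cluster dissimilarities stay below cross-cluster ones ...
    within <- v[outer(grp, grp, "==") & row(v) != col(v)]
    cross <- v[outer(grp, grp, "!=")]
    expect_lt(max(within), min(cross))
    # ... so band means rise with diagonal distance, up to the
    # within-cluster noise scale
    expect_true(all(diff(bandMean) >= -max(within)))
    expect_gt(bandMean[2], bandMean[1])
})
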