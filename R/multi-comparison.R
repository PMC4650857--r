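#' Pairwise dissimilarity matrix over a set of motifs
#'
#' Applies [motifDissimilarity()] to every pair of motifs. Motif labels
#' (or list names) become the matrix labels and must be unique; unlabeled
#' motifs are named `M1..MN`.
#'
#' @param motifs list of at least two [ProbabilityMotif-class] objects of
#'   equal length over one alphabet.
#' @param measures a [MeasurePair-class].
#' @param pad forwarded to [motifDissimilarity()].
#' @return a [DissimilarityMatrix-class].
#' @examples
#' a <- probabilityMotif(rbind(c(1, 0, 0, 0)), "dna", label = "A1")
#' b <- probabilityMotif(rbind(c(0, 1, 0, 0)), "dna", label = "C1")
#' pairwiseDissimilarity(list(a, b))
#' @export
pairwiseDissimilarity <- function(motifs, measures = measurePair(),
                                  pad = FALSE) {
    if (!is.list(motifs) || length(motifs) < 2L)
        stop("need at least two motifs")
    motifs <- lapply(motifs, .asProbability)
    labs <- .motifListLabels(motifs)
    n <- length(motifs)
    v <- matrix(0, n, n, dimnames = list(labs, labs))
    for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
            d <- motifDissimilarity(motifs[[i]], motifs[[j]], measures,
                                    pad = pad)
            v[i, j] <- d
            v[j, i] <- d
        }
    }
    new("DissimilarityMatrix", values = v)
}

.motifListLabels <- function(motifs) {
    labs <- if (!is.null(names(motifs)) && all(nzchar(names(motifs)))) {
        names(motifs)
    } else {
        vapply(motifs, motifLabel, "")
    }
    blank <- !nzchar(labs) | labs == "motif"
    labs[blank] <- paste0("M", which(blank))
    if (anyDuplicated(labs))
        labs <- make.unique(labs, sep = "_")
    labs
}

#' Hierarchical clustering of motifs
#'
#' Agglomerative clustering of the motifs from their dissimilarity matrix
#' via [stats::hclust()]. Complete linkage is the default; average and
#' single linkage are selectable.
#'
#' @param matrix a [DissimilarityMatrix-class].
#' @param linkage `"complete"`, `"average"` or `"single"`.
#' @return an `hclust` object with the motif labels.
#' @export
clusterMotifs <- function(matrix,
                          linkage = c("complete", "average", "single")) {
    linkage <- match.arg(linkage)
    stopifnot(is(matrix, "DissimilarityMatrix"))
    v <- matrix@values
    if (any(!is.finite(v)))
        stop("dissimilarity matrix contains non-finite values")
    stats::hclust(stats::as.dist(v), method = linkage)
}

#' Optimal leaf ordering of a cluster tree
#'
#' Among all leaf orders obtainable by flipping subtrees of the given
#' dendrogram (2^(N-1) orders for N leaves), returns one minimizing the
#' sum of dissimilarities over adjacent leaf pairs, so that neighboring
#' motifs are as similar as possible. Implemented as the standard dynamic
#' program over (leftmost, rightmost) leaf pairs per subtree. Ties are
#' resolved deterministically: candidate endpoints are scanned in
#' label-sorted order with strict improvement, and of the two reversals of
#' the optimum the lexicographically smaller label sequence is returned.
#'
#' @param tree an `hclust` object (see [clusterMotifs()]).
#' @param matrix the [DissimilarityMatrix-class] the tree was built from;
#'   labels must match the tree's leaves.
#' @return character vector: motif labels in optimal order.
#' @export
optimalLeafOrder <- function(tree, matrix) {
    stopifnot(inherits(tree, "hclust"), is(matrix, "DissimilarityMatrix"))
    labs <- tree$labels
    if (is.null(labs) || !setequal(labs, rownames(matrix@values)))
        stop("label mismatch between tree and dissimilarity matrix")
    d <- matrix@values[labs, labs]
    m <- tree$merge
    n <- length(labs)
    if (n == 2L) {
        o <- sort(labs)
        return(o)
    }
    # rank leaves by label so tie scans are deterministic
    labRank <- rank(labs, ties.method = "first")

    solve <- function(node) {
        if (node < 0) {
            lv <- -node
            M <- matrix(0, 1, 1, dimnames = list(lv, lv))
            return(list(leaves = lv, M = M, children = NULL,
                        bt = NULL))
        }
        a <- solve(m[node, 1L])
        b <- solve(m[node, 2L])
        la <- a$leaves[order(labRank[a$leaves])]
        lb <- b$leaves[order(labRank[b$leaves])]
        leaves <- c(a$leaves, b$leaves)
        cl <- as.character(leaves)
        nl <- length(leaves)
        M <- matrix(Inf, nl, nl, dimnames = list(cl, cl))
        btK <- matrix(NA_integer_, nl, nl, dimnames = list(cl, cl))
        btH <- btK
        for (u in la) for (w in lb) {
            cu <- as.character(u); cw <- as.character(w)
            best <- Inf; bk <- NA_integer_; bh <- NA_integer_
            for (k in la) {
                mak <- a$M[cu, as.character(k)]
                if (!is.finite(mak)) next
                for (h in lb) {
                    val <- mak + d[k, h] +
                        b$M[as.character(h), cw]
                    if (val < best) { best <- val; bk <- k; bh <- h }
                }
            }
            M[cu, cw] <- best; btK[cu, cw] <- bk; btH[cu, cw] <- bh
            M[cw, cu] <- best; btK[cw, cu] <- bk; btH[cw, cu] <- bh
        }
        list(leaves = leaves, M = M, children = list(a, b),
             bt = list(K = btK, H = btH), la = la, lb = lb)
    }

    root <- solve(nrow(m))

    # pick the optimal endpoint pair at the root
    best <- Inf; bu <- NA_integer_; bw <- NA_integer_
    la <- root$la; lb <- root$lb
    for (u in la) for (w in lb) {
        val <- root$M[as.character(u), as.character(w)]
        if (val < best) { best <- val; bu <- u; bw <- w }
    }

    reconstruct <- function(nd, u, w) {
        if (is.null(nd$children)) return(nd$leaves)
        a <- nd$children[[1L]]; b <- nd$children[[2L]]
        cu <- as.character(u); cw <- as.character(w)
        k <- nd$bt$K[cu, cw]; h <- nd$bt$H[cu, cw]
        if (u %in% a$leaves) {
            c(reconstruct(a, u, k), reconstruct(b, h, w))
        } else {
            c(reconstruct(b, u, h), reconstruct(a, k, w))
        }
    }
    ord <- labs[reconstruct(root, bu, bw)]
    rev_ord <- rev(ord)
    if (paste(rev_ord, collapse = "\r") < paste(ord, collapse = "\r"))
        ord <- rev_ord
    ord
}

# Linear green -> red interpolation in RGB; t in [0, 1].
.interpolateColor <- function(t, palette = c("#00B000", "#D00000")) {
    ramp <- grDevices::colorRamp(palette)
    rgbv <- ramp(t) / 255
    grDevices::rgb(rgbv[, 1], rgbv[, 2], rgbv[, 3])
}

#' Build the clustered N x N comparison grid
#'
#' The full multi-motif comparison model: all pairwise dissimilarities D,
#' hierarchical clustering, optimal leaf ordering, one difference logo per
#' ordered pair of distinct motifs (the diagonal stays empty; opposing
#' cells are ordinate-mirrored), a shared ordinate bound over all cells,
#' and a background color per cell interpolated linearly in RGB from the
#' green endpoint (minimal off-diagonal D) to the red endpoint (maximal
#' off-diagonal D). When all off-diagonal D are equal, every cell gets the
#' green endpoint.
#'
#' @param motifs list of >= 2 motifs (see [pairwiseDissimilarity()]).
#' @param measures a [MeasurePair-class].
#' @param linkage clustering linkage (see [clusterMotifs()]).
#' @param palette character(2): colors of the similar and dissimilar
#'   endpoints.
#' @param pad forwarded to the pairwise comparisons.
#' @return a [ComparisonGrid-class].
#' @examples
#' ms <- lapply(1:3, function(i)
#'     randomMotif("dna", 6, concentration = 0.5, seed = i,
#'                 label = paste0("m", i)))
#' buildComparisonGrid(ms)
#' @export
buildComparisonGrid <- function(motifs, measures = measurePair(),
                                linkage = "complete",
                                palette = c("#00B000", "#D00000"),
                                pad = FALSE) {
    motifs <- lapply(motifs, .asProbability)
    dm <- pairwiseDissimilarity(motifs, measures, pad = pad)
    labs <- motifLabels(dm)
    tree <- clusterMotifs(dm, linkage)
    ord <- optimalLeafOrder(tree, dm)
    motifs <- motifs[match(ord, labs)]
    n <- length(motifs)
    cells <- vector("list", n)
    colors <- matrix("", n, n, dimnames = list(ord, ord))
    v <- dm@values[ord, ord]
    off <- v[row(v) != col(v)]
    lo <- min(off); hi <- max(off)
    for (i in seq_len(n)) {
        cells[[i]] <- vector("list", n)
        for (j in seq_len(n)) {
            if (i == j) next
            cells[[i]][[j]] <- buildDifferenceLogo(motifs[[i]],
                                                   motifs[[j]], measures,
                                                   pad = pad)
            t <- if (hi > lo) (v[i, j] - lo) / (hi - lo) else 0
            colors[i, j] <- .interpolateColor(t, palette)
        }
    }
    allCells <- unlist(cells, recursive = FALSE)
    allCells <- allCells[!vapply(allCells, is.null, TRUE)]
    shared <- commonOrdinate(allCells)
    headers <- lapply(motifs, buildSequenceLogo)
    new("ComparisonGrid", motifs = motifs, ordering = ord, tree = tree,
        cells = cells, cellColors = colors, dissimilarity = dm,
        sharedOrdinate = shared, headerLogos = headers)
}
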