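# Build a per-position segment data.frame from signed symbol heights.
# Within each side of the axis, segments are stacked in ascending |height|
# from the baseline outward (the most-changed symbol ends up outermost);
# ties broken by alphabet order. Zero heights are dropped.
.stackColumn <- function(symbols, heights, dropTol = 0) {
    keep <- abs(heights) > dropTol
    symbols <- symbols[keep]
    heights <- heights[keep]
    if (!length(heights))
        return(data.frame(symbol = character(), height = numeric(),
                          base = numeric(), stringsAsFactors = FALSE))
    up <- heights > 0
    ordSide <- function(sel) sel[order(abs(heights[sel]),
                                       seq_along(heights)[sel])]
    iUp <- ordSide(which(up))
    iDn <- ordSide(which(!up))
    baseUp <- cumsum(c(0, heights[iUp]))[seq_along(iUp)]
    baseDn <- cumsum(c(0, heights[iDn]))[seq_along(iDn)]
    idx <- c(iUp, iDn)
    data.frame(symbol = symbols[idx], height = heights[idx],
               base = c(baseUp, baseDn), stringsAsFactors = FALSE)
}

# Largest absolute ordinate extent over all columns (0 if all empty).
.maxExtent <- function(cols) {
    ext <- vapply(cols@columns, function(df) {
        if (!nrow(df)) return(0)
        max(abs(c(df$base, df$base + df$height)))
    }, 0)
    if (length(ext)) max(ext) else 0
}

#' Build classic sequence-logo geometry
#'
#' Converts a motif into renderable stacks: at each position, symbols with
#' positive height `p[a] * IC(p)` are stacked upward in ascending height
#' from the baseline, so the most frequent symbol sits on top. Uniform
#' columns have zero information content and yield empty stacks. The
#' default ordinate bound is `log2(|A|)` (2 bits for DNA) for
#' comparability across figures.
#'
#' @param P a [ProbabilityMotif-class] (a [CountMotif-class] is converted
#'   with pseudocount 0).
#' @return a [LogoColumns-class] of kind `"sequence"`.
#' @examples
#' buildSequenceLogo(probabilityMotif(rbind(c(1, 0, 0, 0)), "dna"))
#' @export
buildSequenceLogo <- function(P) {
    P <- .asProbability(P)
    syms <- P@alphabet@symbols
    k <- length(syms)
    cols <- lapply(seq_len(nrow(P@probs)), function(l) {
        .stackColumn(syms, classicSymbolHeights(P@probs[l, ], k))
    })
    new("LogoColumns", kind = "sequence", columns = cols,
        ordinateMax = log2(k), ordinateMin = 0, alphabet = P@alphabet)
}

#' Build difference-logo geometry for a motif pair
#'
#' At each position the stack height is `measures@stackHeight(p, q)` and
#' the signed symbol heights are `measures@symbolWeight(p, q)` times the
#' stack height. Symbols less abundant in the second motif are plotted
#' upward, symbols more abundant in the second motif downward; within each
#' side, segments ascend in magnitude from the baseline. The ordinate is
#' symmetric about 0 and data-driven (falling back to 1 bit when the
#' motifs are identical). Swapping the motifs mirrors every segment across
#' the abscissa.
#'
#' @param P,Q [ProbabilityMotif-class] objects of equal length over the
#'   same alphabet.
#' @param measures a [MeasurePair-class].
#' @param pad pad the shorter motif with uniform columns instead of
#'   erroring on unequal lengths.
#' @return a [LogoColumns-class] of kind `"difference"`.
#' @examples
#' a <- probabilityMotif(rbind(c(1, 0, 0, 0)), "dna")
#' b <- probabilityMotif(rbind(c(0, 1, 0, 0)), "dna")
#' buildDifferenceLogo(a, b)
#' @export
buildDifferenceLogo <- function(P, Q, measures = measurePair(),
                                pad = FALSE) {
    P <- .asProbability(P)
    Q <- .asProbability(Q)
    if (!identical(P@alphabet@symbols, Q@alphabet@symbols))
        stop("motifs must share one alphabet")
    if (nrow(P@probs) != nrow(Q@probs)) {
        if (!pad)
            stop("length mismatch: motifs have ", nrow(P@probs), " and ",
                 nrow(Q@probs), " positions")
        L <- max(nrow(P@probs), nrow(Q@probs))
        P <- padMotif(P, L)
        Q <- padMotif(Q, L)
    }
    syms <- P@alphabet@symbols
    cols <- lapply(seq_len(nrow(P@probs)), function(l) {
        dc <- differenceColumn(P@probs[l, ], Q@probs[l, ], measures, l)
        .stackColumn(syms, dc$symbolHeights)
    })
    obj <- new("LogoColumns", kind = "difference", columns = cols,
               ordinateMax = 1, ordinateMin = -1, alphabet = P@alphabet)
    ext <- .maxExtent(obj)
    if (ext > 0) {
        obj@ordinateMax <- ext
        obj@ordinateMin <- -ext
    }
    obj
}

#' Common ordinate bound over several logos
#'
#' The maximum absolute stack extent over all given logo geometries — the
#' bound every cell of a comparison grid is rendered with, so stack
#' heights are visually comparable across cells. Invariant under the order
#' of the list.
#'
#' @param cols non-empty list of [LogoColumns-class] objects.
#' @return non-negative scalar (0 when every logo is empty).
#' @export
commonOrdinate <- function(cols) {
    if (!is.list(cols) || !length(cols))
        stop("need a non-empty list of LogoColumns")
    max(vapply(cols, function(x) {
        stopifnot(is(x, "LogoColumns"))
        .maxExtent(x)
    }, 0))
}
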