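# Shared sanity check for a pair of per-position distributions.
.checkDistPair <- function(p, q) {
    if (length(p) != length(q))
        stop("alphabet mismatch: distributions have lengths ",
             length(p), " and ", length(q))
    if (any(p < -1e-12) || any(q < -1e-12))
        stop("distributions must be non-negative")
    if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
        stop("distributions must sum to 1")
    invisible(TRUE)
}

#' Information content of a position distribution
#'
#' The conservation of a motif position in bits:
#' `IC(p) = log2(|A|) - H(p)` where `H` is the Shannon entropy with the
#' continuity convention `0 * log2(0) = 0`. Ranges from 0 (uniform) to
#' `log2(|A|)` (one-hot).
#'
#' @param p numeric probability vector over the alphabet.
#' @param alphabetSize number of symbols; defaults to `length(p)`.
#' @return information content in bits.
#' @examples
#' informationContent(c(1, 0, 0, 0))       # 2 bits
#' informationContent(rep(0.25, 4))        # 0 bits
#' @export
informationContent <- function(p, alphabetSize = length(p)) {
    pos <- p[p > 0]
    log2(alphabetSize) + sum(pos * log2(pos))
}

#' Classic sequence-logo symbol heights
#'
#' Per-symbol heights of the traditional sequence logo: each symbol's height
#' is its probability scaled by the position's information content, so the
#' heights are non-negative and sum to the stack height.
#'
#' @inheritParams informationContent
#' @return numeric vector of non-negative heights (bits).
#' @examples
#' classicSymbolHeights(c(0.5, 0.5, 0, 0))  # 0.5 0.5 0 0
#' @export
classicSymbolHeights <- function(p, alphabetSize = length(p)) {
    p * informationContent(p, alphabetSize)
}

#' Jensen-Shannon divergence between two position distributions
#'
#' `JSD(p, q) = 1/2 * KL(p || m) + 1/2 * KL(q || m)` with the mixture
#' `m = (p + q) / 2` and base-2 logarithms, so the value is in bits and
#' bounded by `[0, 1]`; it is symmetric and 0 iff `p = q`. Terms with
#' `p[a] = 0` contribute 0 (continuity convention); `m[a] > 0` whenever
#' either distribution is positive at `a`.
#'
#' @param p,q numeric probability vectors over the same alphabet.
#' @return divergence in bits.
#' @examples
#' jsDivergence(c(1, 0, 0, 0), c(0, 1, 0, 0))          # 1 bit
#' jsDivergence(c(.5, .5, 0, 0), c(.5, 0, .5, 0))      # 0.5 bit
#' @export
jsDivergence <- function(p, q) {
    .checkDistPair(p, q)
    m <- (p + q) / 2
    half <- function(x) {
        i <- x > 0
        sum(x[i] * log2(x[i] / m[i]))
    }
    (half(p) + half(q)) / 2
}

#' Normalized probability differences
#'
#' The signed per-symbol weights of the difference logo:
#' `r[a] = (p[a] - q[a]) / sum_a' |p[a'] - q[a']|` when the distributions
#' differ, and the all-zero vector otherwise ("differ" is tested with
#' tolerance 1e-12 on the maximum componentwise difference, since inputs
#' come from floating-point normalization). The weights sum to 0, their
#' absolute values sum to 1 when `p != q`, and `r(p, q) = -r(q, p)`.
#'
#' @inheritParams jsDivergence
#' @return numeric weight vector.
#' @examples
#' normalizedProbDifference(c(1, 0, 0, 0), c(0, 1, 0, 0))  # 0.5 -0.5 0 0
#' @export
normalizedProbDifference <- function(p, q) {
    .checkDistPair(p, q)
    d <- p - q
    if (max(abs(d)) <= 1e-12) return(rep(0, length(p)))
    d / sum(abs(d))
}

#' Registered stack-height and symbol-weight measures
#'
#' The difference-logo machinery is parameterized by two functions: a stack
#' height `H(p, q)` and a symbol-weight vector `r(p, q)`. Registered stack
#' heights: `"jensenShannon"` (default, [jsDivergence()]),
#' `"sumAbsProbDiff"` (`sum_a |p[a] - q[a]|`) and `"infoContentDiff"`
#' (`|IC(p) - IC(q)|`). Registered symbol weights: `"normalizedProbDiff"`
#' (default, [normalizedProbDifference()]) and `"rawProbDiff"` (`p - q`).
#' Every stack height is symmetric, non-negative and 0 on identical
#' distributions; every symbol weight sums to 0 and is antisymmetric.
#'
#' @param name measure name as listed by `listMeasures()`.
#' @return `stackHeightMeasure()` / `symbolWeightMeasure()` return the
#'   registered function; `listMeasures()` returns a list with character
#'   vectors `$stackHeight` and `$symbolWeight`.
#' @examples
#' listMeasures()
#' stackHeightMeasure("sumAbsProbDiff")(c(1, 0, 0, 0), c(0, 1, 0, 0))  # 2
#' @export
listMeasures <- function() {
    list(stackHeight = names(.STACK_HEIGHTS),
         symbolWeight = names(.SYMBOL_WEIGHTS))
}

.STACK_HEIGHTS <- list(
    jensenShannon = jsDivergence,
    sumAbsProbDiff = function(p, q) {
        .checkDistPair(p, q)
        sum(abs(p - q))
    },
    infoContentDiff = function(p, q) {
        .checkDistPair(p, q)
        abs(informationContent(p) - informationContent(q))
    })

.SYMBOL_WEIGHTS <- list(
    normalizedProbDiff = normalizedProbDifference,
    rawProbDiff = function(p, q) {
        .checkDistPair(p, q)
        p - q
    })

.lookupMeasure <- function(name, table, what) {
    if (is.function(name)) return(name)
    fn <- table[[name]]
    if (is.null(fn))
        stop("unknown ", what, " measure '", name, "'; available: ",
             paste(names(table), collapse = ", "))
    fn
}

#' @rdname listMeasures
#' @export
stackHeightMeasure <- function(name)
    .lookupMeasure(name, .STACK_HEIGHTS, "stack-height")

#' @rdname listMeasures
#' @export
symbolWeightMeasure <- function(name)
    .lookupMeasure(name, .SYMBOL_WEIGHTS, "symbol-weight")

#' Bundle a stack-height and a symbol-weight measure
#'
#' @param stackHeight registered name (see [listMeasures()]) or a
#'   `function(p, q)` returning a non-negative scalar.
#' @param symbolWeight registered name or a `function(p, q)` returning a
#'   signed vector summing to 0.
#' @return a [MeasurePair-class]; the default reproduces the weighted
#'   difference of probabilities (Jensen-Shannon stack heights, normalized
#'   probability-difference symbol weights).
#' @examples
#' measurePair()
#' measurePair("sumAbsProbDiff", "rawProbDiff")
#' @export
measurePair <- function(stackHeight = "jensenShannon",
                        symbolWeight = "normalizedProbDiff") {
    hName <- if (is.character(stackHeight)) stackHeight else "custom"
    rName <- if (is.character(symbolWeight)) symbolWeight else "custom"
    new("MeasurePair",
        stackHeight = stackHeightMeasure(stackHeight),
        symbolWeight = symbolWeightMeasure(symbolWeight),
        names = c(hName, rName))
}

#' Difference-logo column for one position
#'
#' Combines the stack height `H = stackHeight(p, q)` with the signed symbol
#' weights `r = symbolWeight(p, q)` into per-symbol heights `r * H`.
#' With the default measures, the positive heights and the magnitudes of
#' the negative heights each sum to `H / 2` whenever `p != q`: every gain
#' of probability by one symbol is a loss by the others.
#'
#' @inheritParams jsDivergence
#' @param measures a [MeasurePair-class] (default [measurePair()]).
#' @param position 1-based position index stored with the column.
#' @return list with elements `position`, `stackHeight` (bits) and
#'   `symbolHeights` (signed numeric vector).
#' @examples
#' differenceColumn(c(1, 0, 0, 0), c(0, 1, 0, 0))
#' @export
differenceColumn <- function(p, q, measures = measurePair(),
                             position = 1L) {
    H <- measures@stackHeight(p, q)
    r <- measures@symbolWeight(p, q)
    list(position = as.integer(position), stackHeight = H,
         symbolHeights = r * H)
}

#' Scalar dissimilarity between two motifs
#'
#' The sum over all positions of the difference-logo stack heights — the
#' total amount of per-position divergence between the two motifs, in bits
#' under the default Jensen-Shannon stack height. Non-negative, symmetric,
#' 0 iff the motifs are identical, and additive over concatenated position
#' blocks. It is a dissimilarity, not a metric: the Jensen-Shannon
#' divergence without a square root does not satisfy the triangle
#' inequality.
#'
#' @param P,Q [ProbabilityMotif-class] objects over the same alphabet.
#' @param measures a [MeasurePair-class].
#' @param pad if `TRUE`, the shorter motif is extended symmetrically with
#'   uniform columns ([padMotif()]); if `FALSE` (default) unequal lengths
#'   are an error.
#' @return non-negative scalar D.
#' @examples
#' a <- probabilityMotif(rbind(c(1, 0, 0, 0)), "dna")
#' b <- probabilityMotif(rbind(c(0, 1, 0, 0)), "dna")
#' motifDissimilarity(a, b)   # 1 bit
#' @export
motifDissimilarity <- function(P, Q, measures = measurePair(),
                               pad = FALSE) {
    stopifnot(is(P, "ProbabilityMotif"), is(Q, "ProbabilityMotif"))
    if (!identical(P@alphabet@symbols, Q@alphabet@symbols))
        stop("motifs must share one alphabet")
    if (nrow(P@probs) != nrow(Q@probs)) {
        if (!pad)
            stop("length mismatch: motifs have ", nrow(P@probs), " and ",
                 nrow(Q@probs), " positions (set pad = TRUE to pad with ",
                 "uniform columns)")
        L <- max(nrow(P@probs), nrow(Q@probs))
        P <- padMotif(P, L)
        Q <- padMotif(Q, L)
    }
    sum(vapply(seq_len(nrow(P@probs)), function(l)
        measures@stackHeight(P@probs[l, ], Q@probs[l, ]), 0))
}
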