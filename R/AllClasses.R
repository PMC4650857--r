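#' @import methods
NULL

setOldClass("hclust")

#' Alphabet of motif symbols
#'
#' An ordered set of single-character symbols together with display colors.
#' All symbols are case-normalized to upper case and must be unique; an
#' alphabet has at least two symbols.
#'
#' @slot symbols character vector of unique single characters (upper case).
#' @slot name label for the alphabet, e.g. \code{"DNA"}.
#' @slot colors named character vector mapping each symbol to a display color.
#'
#' @seealso [dnaAlphabet()], [rnaAlphabet()], [proteinAlphabet()],
#'   [customAlphabet()]
#' @exportClass Alphabet
setClass("Alphabet",
    representation(symbols = "character", name = "character",
                   colors = "character"))

setValidity("Alphabet", function(object) {
    s <- object@symbols
    if (length(s) < 2L)
        return("alphabet needs at least 2 symbols")
    if (any(nchar(s) != 1L))
        return("alphabet symbols must be single characters")
    if (anyDuplicated(s))
        return("alphabet symbols must be unique")
    if (!identical(s, toupper(s)))
        return("alphabet symbols must be upper case")
    if (!all(s %in% names(object@colors)))
        return("every symbol needs a color")
    if (length(object@name) != 1L)
        return("name must be a single string")
    TRUE
})

#' Position count matrix motif
#'
#' A motif represented as an L x |A| matrix of non-negative integer counts,
#' one row per position, one column per alphabet symbol. Every position must
#' have been observed at least once (positive row sum).
#'
#' @slot alphabet an [Alphabet-class] object.
#' @slot counts numeric matrix (integer-valued), rows = positions.
#' @slot label motif name.
#' @exportClass CountMotif
setClass("CountMotif",
    representation(alphabet = "Alphabet", counts = "matrix",
                   label = "character"))

setValidity("CountMotif", function(object) {
    ct <- object@counts
    if (!is.numeric(ct))
        return("counts must be numeric")
    if (nrow(ct) < 1L)
        return("motif must have at least one position")
    if (ncol(ct) != length(object@alphabet@symbols))
        return("counts must have one column per alphabet symbol")
    if (any(ct < 0))
        return("counts must be non-negative")
    if (any(abs(ct - round(ct)) > 1e-9))
        return("counts must be integers")
    if (any(rowSums(ct) <= 0))
        return("every position must have a positive count sum")
    TRUE
})

#' Probability motif (position weight matrix)
#'
#' A motif represented as an L x |A| row-stochastic matrix: entry (l, a) is
#' the probability of symbol a at position l. Rows sum to 1 within 1e-9.
#'
#' @slot alphabet an [Alphabet-class] object.
#' @slot probs numeric matrix of probabilities, rows = positions.
#' @slot label motif name.
#' @exportClass ProbabilityMotif
setClass("ProbabilityMotif",
    representation(alphabet = "Alphabet", probs = "matrix",
                   label = "character"))

setValidity("ProbabilityMotif", function(object) {
    p <- object@probs
    if (!is.numeric(p))
        return("probs must be numeric")
    if (nrow(p) < 1L)
        return("motif must have at least one position")
    if (ncol(p) != length(object@alphabet@symbols))
        return("probs must have one column per alphabet symbol")
    if (any(p < 0) || any(p > 1))
        return("probabilities must lie in [0, 1]")
    if (any(abs(rowSums(p) - 1) > 1e-9))
        return("every row must sum to 1 (within 1e-9)")
    TRUE
})

#' Pluggable pair of comparison measures
#'
#' Bundles the two functions that define a difference logo: a stack height
#' \code{H(p, q) >= 0} (0 when p = q) and a signed symbol-weight vector
#' \code{r(p, q)} summing to 0. The default pair (Jensen-Shannon divergence
#' and normalized probability differences) is the "weighted difference of
#' probabilities"; see [measurePair()] and [listMeasures()] for alternatives.
#'
#' @slot stackHeight function(p, q) -> non-negative scalar (bits).
#' @slot symbolWeight function(p, q) -> signed vector summing to 0.
#' @slot names character(2): identifiers of the two measures, for reporting.
#' @exportClass MeasurePair
setClass("MeasurePair",
    representation(stackHeight = "function", symbolWeight = "function",
                   names = "character"))

setValidity("MeasurePair", function(object) {
    if (length(object@names) != 2L)
        return("names must have length 2 (stack height, symbol weight)")
    TRUE
})

#' Renderable logo geometry
#'
#' Backend-independent stack geometry for a sequence logo or a difference
#' logo. Each column is a data.frame with columns \code{symbol},
#' \code{height} (signed, bits) and \code{base} (the running offset on the
#' segment's side of the axis: a segment occupies the ordinate interval from
#' \code{min(base, base + height)} to \code{max(base, base + height)}).
#'
#' @slot kind \code{"sequence"} or \code{"difference"}.
#' @slot columns list (length L) of per-position segment data.frames.
#' @slot ordinateMax positive upper bound of the ordinate (bits).
#' @slot ordinateMin lower bound (0 for sequence logos, -ordinateMax for
#'   difference logos).
#' @slot alphabet the [Alphabet-class] the symbols come from.
#' @exportClass LogoColumns
setClass("LogoColumns",
    representation(kind = "character", columns = "list",
                   ordinateMax = "numeric", ordinateMin = "numeric",
                   alphabet = "Alphabet"))

setValidity("LogoColumns", function(object) {
    if (!object@kind %in% c("sequence", "difference"))
        return("kind must be 'sequence' or 'difference'")
    if (object@ordinateMax <= 0)
        return("ordinateMax must be positive")
    if (object@kind == "sequence" && object@ordinateMin != 0)
        return("sequence logos have ordinateMin 0")
    TRUE
})

#' Symmetric motif dissimilarity matrix
#'
#' N x N matrix of pairwise motif dissimilarities D (summed difference-logo
#' stack heights), with motif labels as dimnames. Symmetric within 1e-12,
#' zero diagonal, non-negative.
#'
#' @slot values numeric matrix with identical row/column names.
#' @exportClass DissimilarityMatrix
setClass("DissimilarityMatrix", representation(values = "matrix"))

setValidity("DissimilarityMatrix", function(object) {
    v <- object@values
    if (nrow(v) != ncol(v))
        return("matrix must be square")
    if (is.null(rownames(v)) || is.null(colnames(v)) ||
        !identical(rownames(v), colnames(v)))
        return("row and column labels must be present and identical")
    if (anyDuplicated(rownames(v)))
        return("motif labels must be unique")
    if (any(!is.finite(v)))
        return("matrix entries must be finite")
    if (any(v < 0))
        return("dissimilarities must be non-negative")
    if (any(abs(v - t(v)) > 1e-12))
        return("matrix must be symmetric within 1e-12")
    if (any(abs(diag(v)) > 1e-12))
        return("diagonal must be zero")
    TRUE
})

#' Clustered N x N comparison grid
#'
#' The data model behind the multi-motif comparison figure: motifs in optimal
#' leaf order, the cluster tree, one difference-logo geometry per ordered
#' pair of distinct motifs, a background color per cell interpolated from
#' green (most similar pair) to red (most dissimilar pair), header sequence
#' logos, and the shared ordinate bound used by every cell.
#'
#' @slot motifs list of [ProbabilityMotif-class], in display (leaf) order.
#' @slot ordering character vector of motif labels, the optimal leaf order.
#' @slot tree \code{hclust} object over the motif labels.
#' @slot cells list of lists; \code{cells[[i]][[j]]} is the
#'   [LogoColumns-class] for row-motif i vs column-motif j (NULL on the
#'   diagonal).
#' @slot cellColors character matrix of background colors ("" on diagonal).
#' @slot dissimilarity the [DissimilarityMatrix-class] (original label order).
#' @slot sharedOrdinate common ordinate bound over all cells (bits).
#' @slot headerLogos list of sequence-logo [LogoColumns-class], leaf order.
#' @exportClass ComparisonGrid
setClass("ComparisonGrid",
    representation(motifs = "list", ordering = "character", tree = "hclust",
                   cells = "list", cellColors = "matrix",
                   dissimilarity = "DissimilarityMatrix",
                   sharedOrdinate = "numeric", headerLogos = "list"))

setValidity("ComparisonGrid", function(object) {
    n <- length(object@motifs)
    if (length(object@ordering) != n)
        return("ordering must name every motif")
    if (!all(dim(object@cellColors) == c(n, n)))
        return("cellColors must be N x N")
    TRUE
})

#' Figure parameters for rendering
#'
#' @slot width total canvas width in px (NA = derived from motif length).
#' @slot height canvas height in px.
#' @slot pxPerPosition column width in px used when width is NA.
#' @slot fontSize axis/label font size in px.
#' @slot dpi raster resolution for PNG output.
#' @slot background canvas background color.
#' @exportClass FigureSpec
setClass("FigureSpec",
    representation(width = "numeric", height = "numeric",
                   pxPerPosition = "numeric", fontSize = "numeric",
                   dpi = "numeric", background = "character"))

setValidity("FigureSpec", function(object) {
    if (!is.na(object@width) && object@width <= 0)
        return("width must be positive")
    if (object@height <= 0 || object@pxPerPosition <= 0 ||
        object@fontSize <= 0 || object@dpi <= 0)
        return("figure dimensions must be positive")
    TRUE
})
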