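#' Accessors for motif objects
#'
#' @param x a motif, matrix or grid object.
#' @return \code{alphabet} returns the [Alphabet-class]; \code{motifLength}
#'   the number of positions L; \code{motifLabel} the motif name;
#'   \code{counts} / \code{probs} the underlying L x |A| matrix with symbol
#'   column names; \code{motifLabels} the labels of a
#'   [DissimilarityMatrix-class].
#' @name accessors
#' @aliases alphabet motifLength motifLabel counts probs motifLabels
#' @examples
#' m <- sequencesToCounts(c("ACGT", "ACGA"), dnaAlphabet())
#' motifLength(m)
#' counts(m)
NULL

#' @rdname accessors
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))

#' @rdname accessors
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))

#' @rdname accessors
#' @export
setGeneric("motifLabel", function(x) standardGeneric("motifLabel"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))

#' @rdname accessors
#' @export
setGeneric("motifLabels", function(x) standardGeneric("motifLabels"))

#' @rdname accessors
#' @export
setGeneric("alphabetSymbols", function(x) standardGeneric("alphabetSymbols"))

setMethod("alphabet", "CountMotif", function(x) x@alphabet)
setMethod("alphabet", "ProbabilityMotif", function(x) x@alphabet)
setMethod("alphabet", "LogoColumns", function(x) x@alphabet)

setMethod("motifLength", "CountMotif", function(x) nrow(x@counts))
setMethod("motifLength", "ProbabilityMotif", function(x) nrow(x@probs))

setMethod("motifLabel", "CountMotif", function(x) x@label)
setMethod("motifLabel", "ProbabilityMotif", function(x) x@label)

setMethod("counts", "CountMotif", function(x) {
    m <- x@counts
    colnames(m) <- x@alphabet@symbols
    m
})

setMethod("probs", "ProbabilityMotif", function(x) {
    m <- x@probs
    colnames(m) <- x@alphabet@symbols
    m
})

setMethod("motifLabels", "DissimilarityMatrix", function(x) rownames(x@values))

setMethod("alphabetSymbols", "Alphabet", function(x) x@symbols)
setMethod("alphabetSymbols", "CountMotif", function(x) x@alphabet@symbols)
setMethod("alphabetSymbols", "ProbabilityMotif",
    function(x) x@alphabet@symbols)

#' Extract the dissimilarity values
#'
#' @param x a [DissimilarityMatrix-class].
#' @return the symmetric numeric matrix of D values with motif labels as
#'   dimnames.
#' @export
setGeneric("dissimilarityValues",
    function(x) standardGeneric("dissimilarityValues"))

setMethod("dissimilarityValues", "DissimilarityMatrix", function(x) x@values)
setMethod("dissimilarityValues", "ComparisonGrid",
    function(x) x@dissimilarity@values)

setMethod("show", "Alphabet", function(object) {
    cat(sprintf("%s alphabet: %s\n", object@name,
        paste(object@symbols, collapse = "")))
})

setMethod("show", "CountMotif", function(object) {
    cat(sprintf("CountMotif '%s': %d positions over %s\n",
        object@label, nrow(object@counts), object@alphabet@name))
    print(utils::head(counts(object), 6L))
    if (nrow(object@counts) > 6L) cat("...\n")
})

setMethod("show", "ProbabilityMotif", function(object) {
    cat(sprintf("ProbabilityMotif '%s': %d positions over %s\n",
        object@label, nrow(object@probs), object@alphabet@name))
    print(round(utils::head(probs(object), 6L), 3))
    if (nrow(object@probs) > 6L) cat("...\n")
})

setMethod("show", "MeasurePair", function(object) {
    cat(sprintf("MeasurePair: stack height '%s', symbol weight '%s'\n",
        object@names[1L], object@names[2L]))
})

setMethod("show", "LogoColumns", function(object) {
    nseg <- sum(vapply(object@columns, nrow, 0L))
    cat(sprintf("%s logo geometry: %d positions, %d segments, ordinate [%g, %g] bits\n",
        object@kind, length(object@columns), nseg,
        object@ordinateMin, object@ordinateMax))
})

setMethod("show", "DissimilarityMatrix", function(object) {
    cat(sprintf("DissimilarityMatrix over %d motifs\n", nrow(object@values)))
    print(round(object@values, 4))
})

setMethod("show", "ComparisonGrid", function(object) {
    cat(sprintf("ComparisonGrid: %d motifs, leaf order: %s\n",
        length(object@motifs), paste(object@ordering, collapse = " ")))
    cat(sprintf("shared ordinate bound: %g bits\n", object@sharedOrdinate))
})
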