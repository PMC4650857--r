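#' Tally aligned sequences into a count motif
#'
#' Counts, per position, how many sequences carry each alphabet symbol. All
#' sequences must share a common length L. Symbols outside the alphabet
#' (gaps '-', '.', ambiguity codes such as N or X) either raise an error
#' (`unknownPolicy = "error"`) or are skipped (`"skip"`, the default for
#' alignment input): a skipped symbol contributes to no count cell, so
#' column sums equal the number of non-skipped sequences at that position.
#' A position at which every sequence was skipped is a degenerate column and
#' raises an error.
#'
#' @param sequences character vector of equal-length strings (case is
#'   normalized to upper case).
#' @param alphabet an [Alphabet-class] or a name accepted by
#'   [resolveAlphabet()].
#' @param unknownPolicy `"skip"` or `"error"`.
#' @param label motif name.
#' @return a [CountMotif-class].
#' @examples
#' sequencesToCounts(c("ACGT", "ACGA"), dnaAlphabet())
#' @export
sequencesToCounts <- function(sequences, alphabet,
                              unknownPolicy = c("skip", "error"),
                              label = "motif") {
    unknownPolicy <- match.arg(unknownPolicy)
    alphabet <- resolveAlphabet(alphabet)
    if (length(sequences) < 1L)
        stop("need at least one sequence")
    sequences <- toupper(sequences)
    L <- nchar(sequences[1L])
    if (L < 1L)
        stop("sequences must have length >= 1")
    if (any(nchar(sequences) != L))
        stop("length mismatch: all sequences must have the common length ",
             L, " (offending sequence ",
             which(nchar(sequences) != L)[1L], ")")
    chars <- matrix(unlist(strsplit(sequences, ""), use.names = FALSE),
                    nrow = length(sequences), ncol = L, byrow = TRUE)
    syms <- alphabet@symbols
    unknown <- !(chars %in% syms)
    if (any(unknown) && unknownPolicy == "error") {
        bad <- chars[unknown][1L]
        stop("symbol '", bad, "' not in ", alphabet@name, " alphabet")
    }
    ct <- vapply(seq_len(L), function(l) {
        tabulate(match(chars[, l], syms), nbins = length(syms))
    }, numeric(length(syms)))
    ct <- t(ct)                       # L x |A|
    if (any(rowSums(ct) == 0))
        stop("degenerate column: position ",
             which(rowSums(ct) == 0)[1L],
             " has no symbol from the alphabet")
    new("CountMotif", alphabet = alphabet, counts = ct, label = label)
}

#' Convert counts to probabilities
#'
#' Estimates per-position symbol probabilities as relative frequencies with
#' optional additive (Laplace) smoothing:
#' `p[l, a] = (n[l, a] + pseudocount) / (sum_a n[l, a] + |A| * pseudocount)`.
#'
#' @param motif a [CountMotif-class].
#' @param pseudocount non-negative smoothing constant added to every cell
#'   (default 0; command-line count input defaults to 1).
#' @return a [ProbabilityMotif-class] with the same label.
#' @examples
#' m <- sequencesToCounts(c("ACGT", "ACGA"), dnaAlphabet())
#' probs(countsToProbabilities(m))
#' @export
countsToProbabilities <- function(motif, pseudocount = 0) {
    stopifnot(is(motif, "CountMotif"))
    if (length(pseudocount) != 1L || !is.finite(pseudocount) ||
        pseudocount < 0)
        stop("pseudocount must be a single non-negative number")
    ct <- motif@counts + pseudocount
    rs <- rowSums(ct)
    if (any(rs <= 0))
        stop("degenerate column: all-zero counts with pseudocount 0 at ",
             "position ", which(rs <= 0)[1L])
    new("ProbabilityMotif", alphabet = motif@alphabet, probs = ct / rs,
        label = motif@label)
}

#' Validate and construct a probability motif from a raw matrix
#'
#' Checks that every entry is non-negative and that every row sums to 1
#' within `tolerance`; rows inside the tolerance are renormalized to sum to
#' exactly 1. Rows outside the tolerance, or negative entries, are errors.
#'
#' @param matrix numeric L x |A| matrix (rows = positions).
#' @param alphabet an [Alphabet-class] or name.
#' @param tolerance permitted absolute deviation of a row sum from 1.
#' @param label motif name.
#' @return a [ProbabilityMotif-class].
#' @examples
#' probabilityMotif(rbind(c(1, 0, 0, 0), c(.25, .25, .25, .25)), "dna")
#' @export
probabilityMotif <- function(matrix, alphabet, tolerance = 1e-6,
                             label = "motif") {
    alphabet <- resolveAlphabet(alphabet)
    m <- as.matrix(matrix)
    storage.mode(m) <- "double"
    if (ncol(m) != length(alphabet@symbols))
        stop("matrix has ", ncol(m), " columns but alphabet has ",
             length(alphabet@symbols), " symbols")
    if (any(m < 0))
        stop("negative probability entries are not allowed")
    rs <- rowSums(m)
    bad <- abs(rs - 1) > tolerance
    if (any(bad))
        stop("row ", which(bad)[1L], " sums to ", format(rs[bad][1L]),
             ", outside 1 +/- ", format(tolerance))
    new("ProbabilityMotif", alphabet = alphabet, probs = m / rs,
        label = label)
}

#' Draw a random motif from symmetric Dirichlet columns
#'
#' Each position's symbol distribution is drawn independently from a
#' symmetric Dirichlet with the given concentration: small concentrations
#' (<< 1) give sharply peaked, well-conserved columns; large concentrations
#' give near-uniform columns. Deterministic for a fixed seed; the caller's
#' random-number state is left untouched when a seed is given.
#'
#' @param alphabet an [Alphabet-class] or name.
#' @param length number of positions, >= 1.
#' @param concentration positive Dirichlet concentration parameter.
#' @param seed optional integer seed.
#' @param label motif name.
#' @return a [ProbabilityMotif-class].
#' @examples
#' randomMotif("dna", length = 7, concentration = 0.5, seed = 1)
#' @export
randomMotif <- function(alphabet, length, concentration = 1, seed = NULL,
                        label = "random") {
    alphabet <- resolveAlphabet(alphabet)
    if (length(length) != 1L || length < 1 || length != round(length))
        stop("length must be a positive integer")
    if (length(concentration) != 1L || !is.finite(concentration) ||
        concentration <= 0)
        stop("concentration must be a positive number")
    k <- base::length(alphabet@symbols)
    draw <- function() {
        g <- stats::rgamma(length * k, shape = concentration, rate = 1)
        # guard against all-zero rows from underflow at tiny concentrations
        g[g <= 0 | !is.finite(g)] <- .Machine$double.xmin
        m <- matrix(g, nrow = length, ncol = k)
        m / rowSums(m)
    }
    if (!is.null(seed)) {
        p <- withSeed(as.integer(seed), draw)
    } else {
        p <- draw()
    }
    new("ProbabilityMotif", alphabet = alphabet, probs = p, label = label)
}

# Run fn under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
withSeed <- function(seed, fn) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(seed)
    fn()
}

#' Pad a motif to a target length with uniform columns
#'
#' Extends a motif symmetrically (extra column on the right when the total
#' padding is odd) with uniform columns. A uniform column is maximally
#' non-committal: compared against any other column it contributes the
#' least-assumptive difference, and against another uniform column exactly
#' zero.
#'
#' @param motif a [ProbabilityMotif-class].
#' @param targetLength desired length >= current length.
#' @return a padded [ProbabilityMotif-class].
#' @export
padMotif <- function(motif, targetLength) {
    stopifnot(is(motif, "ProbabilityMotif"))
    L <- nrow(motif@probs)
    if (targetLength < L)
        stop("targetLength must be >= motif length")
    if (targetLength == L) return(motif)
    k <- length(motif@alphabet@symbols)
    d <- targetLength - L
    left <- d %/% 2L
    right <- d - left
    u <- matrix(1 / k, nrow = 1L, ncol = k)
    p <- rbind(u[rep(1L, left), , drop = FALSE], motif@probs,
               u[rep(1L, right), , drop = FALSE])
    new("ProbabilityMotif", alphabet = motif@alphabet, probs = p,
        label = motif@label)
}

# Coerce any motif input (CountMotif or ProbabilityMotif) to probabilities.
.asProbability <- function(motif, pseudocount = 0) {
    if (is(motif, "ProbabilityMotif")) return(motif)
    if (is(motif, "CountMotif"))
        return(countsToProbabilities(motif, pseudocount))
    stop("expected a CountMotif or ProbabilityMotif")
}
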