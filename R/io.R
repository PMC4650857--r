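#' Read motifs from JASPAR-style PFM text
#'
#' Parses the plain-text JASPAR position frequency matrix dialect: an
#' optional header line `">ID name"` per record followed by one line per
#' symbol, `A [ 3 5 0 ]`, with the brackets optional (`A 3 5 0`). Symbol
#' rows may appear in any order; headerless single-motif files are
#' accepted. The alphabet is inferred from the row letters (ACGT = DNA,
#' ACGU = RNA, the 20 amino acids = protein, anything else = custom)
#' unless one is supplied. Integer-valued matrices become
#' [CountMotif-class] objects; matrices whose columns sum to 1 become
#' [ProbabilityMotif-class] objects.
#'
#' @param path file path, or a character vector of lines via `text =`.
#' @param text optional character scalar/vector of raw text instead of a
#'   file.
#' @param alphabet optional [Alphabet-class] or name overriding inference.
#' @return list of motifs ([CountMotif-class] or [ProbabilityMotif-class]);
#'   records without a header are labeled from the file name stem.
#' @examples
#' readJaspar(text = ">M1\nA [ 2 0 ]\nC [ 0 2 ]\nG [ 0 0 ]\nT [ 0 0 ]")
#' @export
readJaspar <- function(path = NULL, text = NULL, alphabet = NULL) {
    if (is.null(text)) {
        if (is.null(path) || !file.exists(path))
            stop("file not found: ", path)
        lines <- readLines(path, warn = FALSE)
        stem <- sub("\\.[^.]*$", "", basename(path))
    } else {
        lines <- unlist(strsplit(text, "\n"), use.names = FALSE)
        stem <- "motif"
    }
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        stop("empty JASPAR input")
    # split into records at '>' headers
    isHdr <- startsWith(lines, ">")
    recId <- cumsum(isHdr)
    if (recId[1L] == 0L) recId <- recId + 1L   # headerless first record
    out <- list()
    for (r in unique(recId)) {
        block <- lines[recId == r]
        label <- stem
        if (startsWith(block[1L], ">")) {
            label <- trimws(sub("^>\\s*", "", block[1L]))
            label <- strsplit(label, "\\s+")[[1L]][1L]
            if (!nzchar(label)) label <- stem
            block <- block[-1L]
        }
        if (!length(block))
            stop("JASPAR record '", label, "' has no matrix rows")
        out[[length(out) + 1L]] <- .parseJasparBlock(block, label,
                                                     alphabet)
    }
    out
}

.parseJasparBlock <- function(block, label, alphabet) {
    syms <- character(length(block))
    rows <- vector("list", length(block))
    for (i in seq_along(block)) {
        ln <- block[i]
        mm <- regmatches(ln,
            regexec("^([A-Za-z])\\s*[\\[]?\\s*(.*?)\\s*[\\]]?\\s*$",
                    ln, perl = TRUE))[[1L]]
        if (length(mm) != 3L)
            stop("cannot parse JASPAR row: '", ln, "'")
        syms[i] <- toupper(mm[2L])
        nums <- strsplit(trimws(mm[3L]), "\\s+")[[1L]]
        vals <- suppressWarnings(as.numeric(nums))
        if (!length(vals) || anyNA(vals))
            stop("non-numeric values in JASPAR row: '", ln, "'")
        rows[[i]] <- vals
    }
    if (anyDuplicated(syms))
        stop("duplicate symbol row '", syms[anyDuplicated(syms)],
             "' in JASPAR record '", label, "'")
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
        stop("ragged JASPAR record '", label, "': rows have ",
             paste(unique(lens), collapse = ", "), " columns")
    if (is.null(alphabet)) {
        alphabet <- .inferAlphabet(syms)
    } else {
        alphabet <- resolveAlphabet(alphabet)
    }
    if (!setequal(syms, alphabet@symbols))
        stop("JASPAR record '", label, "' rows (",
             paste(sort(syms), collapse = ""),
             ") do not match the ", alphabet@name, " alphabet")
    m <- do.call(rbind, rows)[match(alphabet@symbols, syms), ,
                              drop = FALSE]
    m <- t(m)                               # L x |A|
    if (all(abs(m - round(m)) < 1e-9)) {
        new("CountMotif", alphabet = alphabet, counts = round(m),
            label = label)
    } else if (all(abs(rowSums(m) - 1) < 1e-4)) {
        probabilityMotif(m, alphabet, tolerance = 1e-4, label = label)
    } else {
        stop("JASPAR record '", label, "' is neither integer counts nor ",
             "row-stochastic probabilities")
    }
}

.inferAlphabet <- function(syms) {
    s <- sort(toupper(syms))
    if (identical(s, c("A", "C", "G", "T"))) return(dnaAlphabet())
    if (identical(s, c("A", "C", "G", "U"))) return(rnaAlphabet())
    prot <- proteinAlphabet()
    if (setequal(s, prot@symbols)) return(prot)
    customAlphabet(s)
}

#' Write a motif as JASPAR-style PFM text
#'
#' Inverse of [readJaspar()]: a `">label"` header followed by one
#' bracketed row per alphabet symbol.
#'
#' @param motif a [CountMotif-class] or [ProbabilityMotif-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeJaspar <- function(motif, path) {
    m <- if (is(motif, "CountMotif")) counts(motif) else probs(motif)
    syms <- alphabetSymbols(motif)
    fmt <- if (is(motif, "CountMotif")) {
        function(x) format(x, scientific = FALSE, trim = TRUE)
    } else {
        function(x) sprintf("%.9g", x)
    }
    lines <- c(paste0(">", motifLabel(motif)),
               vapply(seq_along(syms), function(i)
                   paste0(syms[i], " [ ",
                          paste(fmt(m[, i]), collapse = " "), " ]"), ""))
    writeLines(lines, path)
    invisible(path)
}

#' Read a motif from a plain tabular matrix
#'
#' Whitespace- or tab-delimited numeric matrix with optional header row
#' and/or label column. The orientation flag states whether rows are
#' symbols (`"symbols_by_positions"`) or positions
#' (`"positions_by_symbols"`); it is never guessed — when the matrix is
#' square and no orientation is given, the call errors rather than risk a
#' silent transposition.
#'
#' @param path input file.
#' @param alphabet an [Alphabet-class] or name.
#' @param orientation `"symbols_by_positions"`, `"positions_by_symbols"`,
#'   or `NULL` (infer only when unambiguous).
#' @param kind `"counts"` or `"probabilities"`.
#' @param label motif name (defaults to the file name stem).
#' @return a [CountMotif-class] or [ProbabilityMotif-class].
#' @export
readTabularMotif <- function(path, alphabet,
                             orientation = NULL,
                             kind = c("counts", "probabilities"),
                             label = NULL) {
    kind <- match.arg(kind)
    alphabet <- resolveAlphabet(alphabet)
    if (!file.exists(path))
        stop("file not found: ", path)
    if (is.null(label))
        label <- sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines))
        stop("empty matrix file: ", path)
    toks <- lapply(lines, function(l) strsplit(trimws(l), "[\t ]+")[[1L]])
    isNum <- function(x) !anyNA(suppressWarnings(as.numeric(x)))
    # optional header row: first line entirely non-numeric
    if (!any(vapply(toks[[1L]], isNum, TRUE)))
        toks <- toks[-1L]
    if (!length(toks))
        stop("no numeric rows in matrix file: ", path)
    # optional label column: every row starts with a non-numeric token
    if (all(vapply(toks, function(t) length(t) > 1L && !isNum(t[1L]),
                   TRUE)))
        toks <- lapply(toks, `[`, -1L)
    if (length(unique(lengths(toks))) != 1L)
        stop("ragged matrix in ", path, ": rows have ",
             paste(unique(lengths(toks)), collapse = ", "), " columns")
    m <- do.call(rbind, lapply(toks, as.numeric))
    if (anyNA(m))
        stop("non-numeric matrix entries in ", path)
    k <- length(alphabet@symbols)
    fitsRows <- nrow(m) == k
    fitsCols <- ncol(m) == k
    if (!fitsRows && !fitsCols)
        stop("shape error: ", nrow(m), " x ", ncol(m),
             " matrix does not fit a ", k, "-symbol alphabet in either ",
             "orientation")
    if (is.null(orientation)) {
        if (fitsRows && fitsCols)
            stop("ambiguous square matrix: specify the orientation ",
                 "(symbols_by_positions or positions_by_symbols)")
        orientation <- if (fitsRows) "symbols_by_positions"
                       else "positions_by_symbols"
    }
    orientation <- match.arg(orientation, c("symbols_by_positions",
                                            "positions_by_symbols"))
    if (orientation == "symbols_by_positions") {
        if (!fitsRows)
            stop("shape error: expected ", k, " symbol rows, found ",
                 nrow(m))
        m <- t(m)
    } else if (!fitsCols) {
        stop("shape error: expected ", k, " symbol columns, found ",
             ncol(m))
    }
    if (kind == "counts") {
        new("CountMotif", alphabet = alphabet, counts = m, label = label)
    } else {
        probabilityMotif(m, alphabet, tolerance = 1e-4, label = label)
    }
}

#' Write a motif as a tabular matrix (positions by symbols)
#'
#' TSV with a symbol header row; one row per position. Probabilities are
#' written with 9 significant digits so a read-back agrees within 1e-6.
#'
#' @inheritParams writeJaspar
#' @export
writeTabularMotif <- function(motif, path) {
    m <- if (is(motif, "CountMotif")) counts(motif) else probs(motif)
    fmt <- if (is(motif, "CountMotif")) {
        function(x) format(x, scientific = FALSE, trim = TRUE)
    } else {
        function(x) sprintf("%.9g", x)
    }
    lines <- c(paste(colnames(m), collapse = "\t"),
               vapply(seq_len(nrow(m)), function(i)
                   paste(fmt(m[i, ]), collapse = "\t"), ""))
    writeLines(lines, path)
    invisible(path)
}

#' Read an aligned FASTA file as a count motif
#'
#' All records must share one length; unknown symbols follow
#' `unknownPolicy` as in [sequencesToCounts()] (gaps and ambiguity codes
#' are skipped by default). With `rnaAsDna = TRUE` and a DNA alphabet,
#' U is remapped to T; no remapping ever happens silently.
#'
#' @param path FASTA file.
#' @param alphabet an [Alphabet-class] or name.
#' @param unknownPolicy `"skip"` or `"error"`.
#' @param rnaAsDna map U to T (DNA alphabet only).
#' @param label motif name (defaults to the file name stem).
#' @return a [CountMotif-class].
#' @export
readFastaMotif <- function(path, alphabet,
                           unknownPolicy = c("skip", "error"),
                           rnaAsDna = FALSE, label = NULL) {
    unknownPolicy <- match.arg(unknownPolicy)
    alphabet <- resolveAlphabet(alphabet)
    if (!file.exists(path))
        stop("file not found: ", path)
    if (is.null(label))
        label <- sub("\\.[^.]*$", "", basename(path))
    seqs <- Biostrings::readBStringSet(path)
    if (!length(seqs))
        stop("no sequences in FASTA file ", path)
    w <- Biostrings::width(seqs)
    if (length(unique(w)) != 1L) {
        bad <- which(w != w[1L])[1L]
        stop("length mismatch in FASTA alignment: record '",
             names(seqs)[bad], "' has length ", w[bad],
             " but the alignment length is ", w[1L])
    }
    s <- toupper(as.character(seqs))
    if (rnaAsDna) {
        if (alphabet@name != "DNA")
            stop("rnaAsDna requires the DNA alphabet")
        s <- gsub("U", "T", s, fixed = TRUE)
    }
    sequencesToCounts(unname(s), alphabet, unknownPolicy, label = label)
}

#' Write / read a dissimilarity matrix as TSV
#'
#' Header row and first column carry the motif labels; values use 9
#' significant digits with a "." decimal separator regardless of locale,
#' so `readDistanceMatrix(writeDistanceMatrix(M))` agrees with `M` within
#' 1e-6.
#'
#' @param matrix a [DissimilarityMatrix-class].
#' @param path file path.
#' @return `writeDistanceMatrix` invisibly returns the path;
#'   `readDistanceMatrix` returns a [DissimilarityMatrix-class].
#' @export
writeDistanceMatrix <- function(matrix, path) {
    stopifnot(is(matrix, "DissimilarityMatrix"))
    v <- matrix@values
    labs <- rownames(v)
    lines <- c(paste(c("", labs), collapse = "\t"),
               vapply(seq_len(nrow(v)), function(i)
                   paste(c(labs[i], sprintf("%.9g", v[i, ])),
                         collapse = "\t"), ""))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            row.names = 1L, check.names = FALSE)
    v <- as.matrix(df)
    # symmetrize away formatting round-off
    v <- (v + t(v)) / 2
    diag(v) <- 0
    new("DissimilarityMatrix", values = v)
}

#' Write a cluster tree in Newick format
#'
#' Serializes an `hclust` tree with branch lengths under the ultrametric
#' convention that a node at merge height h sits at depth h/2, so a
#' two-leaf tree merged at height h yields `(A:h/2,B:h/2);`. Labels
#' containing whitespace or Newick metacharacters are single-quoted.
#'
#' @param tree an `hclust` object.
#' @param path output file.
#' @return invisibly, the Newick string.
#' @export
writeNewick <- function(tree, path) {
    stopifnot(inherits(tree, "hclust"))
    m <- tree$merge
    h <- tree$height
    labs <- tree$labels
    q <- function(l) {
        if (grepl("[][\\s():;,']", l, perl = TRUE))
            paste0("'", gsub("'", "''", l), "'")
        else l
    }
    fmt <- function(x) sprintf("%.9g", x)
    sub <- function(node, parentDepth) {
        if (node < 0)
            return(paste0(q(labs[-node]), ":", fmt(parentDepth)))
        depth <- h[node] / 2
        paste0("(", sub(m[node, 1L], depth), ",",
               sub(m[node, 2L], depth), "):",
               fmt(parentDepth - depth))
    }
    root <- nrow(m)
    depth <- h[root] / 2
    nwk <- paste0("(", sub(m[root, 1L], depth), ",",
                  sub(m[root, 2L], depth), ");")
    writeLines(nwk, path)
    invisible(nwk)
}
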