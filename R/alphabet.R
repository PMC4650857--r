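# Amino-acid colors follow a chemistry grouping: small/polar orange,
# hydrophobic green, acidic red, basic blue, amide/aromatic-polar magenta.
.PROTEIN_COLORS <- c(
    G = "#E69F00", S = "#E69F00", T = "#E69F00", Y = "#CC44CC", C = "#009E73",
    Q = "#CC44CC", N = "#CC44CC",
    A = "#009E73", V = "#009E73", L = "#009E73", I = "#009E73", P = "#009E73",
    F = "#009E73", M = "#009E73", W = "#009E73",
    D = "#D00000", E = "#D00000",
    K = "#0000CC", R = "#0000CC", H = "#0000CC")

.DNA_COLORS <- c(A = "#00A000", C = "#0000CC", G = "#FFA500", T = "#D00000")
.RNA_COLORS <- c(A = "#00A000", C = "#0000CC", G = "#FFA500", U = "#D00000")

#' Construct an alphabet
#'
#' `customAlphabet()` builds an [Alphabet-class] from an arbitrary symbol set;
#' `dnaAlphabet()`, `rnaAlphabet()` and `proteinAlphabet()` are the standard
#' biopolymer alphabets with conventional display colors (DNA/RNA: A green,
#' C blue, G orange, T/U red; amino acids by chemistry class).
#'
#' @param symbols character vector of single characters (or one string that
#'   is split into characters); case-normalized to upper case.
#' @param name label for the alphabet.
#' @param colors optional named vector of colors per symbol; unnamed symbols
#'   get colors from a default palette.
#' @return an [Alphabet-class] object.
#' @examples
#' dnaAlphabet()
#' customAlphabet("ABX", name = "toy")
#' @export
customAlphabet <- function(symbols, name = "custom", colors = NULL) {
    if (length(symbols) == 1L && nchar(symbols) > 1L)
        symbols <- strsplit(symbols, "")[[1L]]
    symbols <- toupper(as.character(symbols))
    pal <- grDevices::hcl.colors(max(length(symbols), 3L), "Dark 3")
    full <- structure(pal[seq_along(symbols)], names = symbols)
    if (!is.null(colors)) full[names(colors)] <- colors
    known <- c(.DNA_COLORS, .PROTEIN_COLORS)
    if (is.null(colors)) {
        hit <- symbols %in% names(known)
        full[hit] <- known[symbols[hit]]
    }
    new("Alphabet", symbols = symbols, name = name, colors = full)
}

#' @rdname customAlphabet
#' @export
dnaAlphabet <- function()
    new("Alphabet", symbols = c("A", "C", "G", "T"), name = "DNA",
        colors = .DNA_COLORS)

#' @rdname customAlphabet
#' @export
rnaAlphabet <- function()
    new("Alphabet", symbols = c("A", "C", "G", "U"), name = "RNA",
        colors = .RNA_COLORS)

#' @rdname customAlphabet
#' @export
proteinAlphabet <- function() {
    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
            "P", "Q", "R", "S", "T", "V", "W", "Y")
    new("Alphabet", symbols = aa, name = "protein",
        colors = .PROTEIN_COLORS[aa])
}

#' Resolve an alphabet from a name
#'
#' Accepts `"dna"`, `"rna"`, `"protein"` or `"custom:<symbols>"`
#' (case-insensitive), or an [Alphabet-class] object which is passed through.
#'
#' @param x alphabet name or object.
#' @return an [Alphabet-class].
#' @export
resolveAlphabet <- function(x) {
    if (is(x, "Alphabet")) return(x)
    stopifnot(is.character(x), length(x) == 1L)
    lx <- tolower(x)
    if (lx == "dna") return(dnaAlphabet())
    if (lx == "rna") return(rnaAlphabet())
    if (lx == "protein") return(proteinAlphabet())
    if (startsWith(lx, "custom:"))
        return(customAlphabet(substring(x, 8L)))
    stop("unknown alphabet '", x,
         "'; use dna, rna, protein or custom:<symbols>")
}
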