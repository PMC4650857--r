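#' Toy single-column motif pairs with known divergences
#'
#' Four canonical length-1 DNA motif pairs illustrating the
#' Jensen-Shannon stack height: (1) two different fully conserved bases,
#' 1 bit; (2) two disjoint 50/50 base pairs, 1 bit; (3) two 50/50 base
#' pairs sharing one base, 0.5 bit; (4) two differentially abundant bases
#' tuned so the divergence is 0.25 bit. Case 4's distributions are an
#' approximation constructed here (the mixing weight is solved
#' numerically from the 0.25-bit requirement), the other three are exact.
#'
#' @return named list of cases, each a list with [ProbabilityMotif-class]
#'   elements `first` and `second` and the expected `divergence` in bits.
#' @examples
#' tp <- toyMotifPairs()
#' jsDivergence(probs(tp$case1$first)[1, ], probs(tp$case1$second)[1, ])
#' @export
toyMotifPairs <- function() {
    dna <- dnaAlphabet()
    mk <- function(p, lab) probabilityMotif(rbind(p), dna, label = lab)
    # case 4: solve JSD((x,1-x,0,0),(1-x,x,0,0)) = 0.25 for x in (0.5, 1)
    x <- stats::uniroot(function(x)
        jsDivergence(c(x, 1 - x, 0, 0), c(1 - x, x, 0, 0)) - 0.25,
        c(0.5 + 1e-9, 1 - 1e-9), tol = 1e-12)$root
    list(
        case1 = list(first = mk(c(1, 0, 0, 0), "case1_first"),
                     second = mk(c(0, 1, 0, 0), "case1_second"),
                     divergence = 1),
        case2 = list(first = mk(c(0.5, 0.5, 0, 0), "case2_first"),
                     second = mk(c(0, 0, 0.5, 0.5), "case2_second"),
                     divergence = 1),
        case3 = list(first = mk(c(0.5, 0.5, 0, 0), "case3_first"),
                     second = mk(c(0.5, 0, 0.5, 0), "case3_second"),
                     divergence = 0.5),
        case4 = list(first = mk(c(x, 1 - x, 0, 0), "case4_first"),
                     second = mk(c(1 - x, x, 0, 0), "case4_second"),
                     divergence = 0.25))
}

#' Write a deterministic fixture data set
#'
#' Produces, under `dir`: the four toy motif pairs of [toyMotifPairs()]
#' as tabular probability matrices (`caseN_first.tsv`,
#' `caseN_second.tsv`), one JASPAR counts file of three random motifs per
#' Dirichlet concentration in `concentrations` (counts are probabilities
#' scaled to depth 1000 and rounded), and one aligned FASTA file of
#' sequences sampled from a random motif. All output is deterministic for
#' a fixed seed.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @param concentrations Dirichlet concentrations for the random motif
#'   sets.
#' @param motifLength length of the random motifs.
#' @return invisibly, character vector of written file paths.
#' @export
writeFixtureMotifs <- function(dir, seed = 1,
                               concentrations = c(0.5, 1, 5),
                               motifLength = 8L) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character()
    tp <- toyMotifPairs()
    for (nm in names(tp)) {
        for (side in c("first", "second")) {
            p <- file.path(dir, paste0(nm, "_", side, ".tsv"))
            writeTabularMotif(tp[[nm]][[side]], p)
            paths <- c(paths, p)
        }
    }
    files <- withSeed(as.integer(seed), function() {
        written <- character()
        for (conc in concentrations) {
            ms <- lapply(1:3, function(i)
                randomMotif("dna", motifLength, conc,
                            label = sprintf("dirichlet_c%g_m%d", conc, i)))
            p <- file.path(dir, sprintf("dirichlet_c%g.pfm", conc))
            txt <- unlist(lapply(ms, function(m) {
                ct <- round(probs(m) * 1000)
                c(paste0(">", motifLabel(m)),
                  vapply(seq_len(ncol(ct)), function(a)
                      paste0(colnames(ct)[a], " [ ",
                             paste(ct[, a], collapse = " "), " ]"), ""))
            }))
            writeLines(txt, p)
            written <- c(written, p)
        }
        src <- randomMotif("dna", motifLength, 0.5, label = "alignment")
        seqs <- vapply(seq_len(40L), function(i) {
            paste(vapply(seq_len(motifLength), function(l)
                sample(alphabetSymbols(src), 1L,
                       prob = probs(src)[l, ]), ""), collapse = "")
        }, "")
        p <- file.path(dir, "alignment.fasta")
        writeLines(as.vector(rbind(paste0(">seq", seq_along(seqs)),
                                   seqs)), p)
        c(written, p)
    })
    invisible(c(paths, files))
}
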