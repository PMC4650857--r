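# Shared fixtures and independent oracles used across the suite.

# random probability vector over k symbols (uses the test RNG)
rand_dist <- function(k = 4L) {
    x <- runif(k)
    x / sum(x)
}

# random probability motif built through the validating constructor only
rand_pm <- function(L, alpha = dnaAlphabet(), label = "motif") {
    k <- length(alphabetSymbols(alpha))
    probabilityMotif(t(replicate(L, rand_dist(k))), alpha, label = label)
}

# Independent Jensen-Shannon oracle: textbook 1/2 KL(p||m) + 1/2 KL(q||m)
# written term by term with natural logs, deliberately not sharing code
# with the package implementation.
js_oracle <- function(p, q) {
    m <- (p + q) / 2
    kl <- function(a, b) {
        s <- 0
        for (i in seq_along(a))
            if (a[i] > 0) s <- s + a[i] * (log(a[i]) - log(b[i]))
        s / log(2)
    }
    0.5 * kl(p, m) + 0.5 * kl(q, m)
}

# All leaf orders reachable by flipping subtrees of an hclust tree
# (2^(N-1) orders), as a list of label vectors.
flip_orders <- function(tree) {
    m <- tree$merge
    rec <- function(node) {
        if (node < 0) return(list(tree$labels[-node]))
        a <- rec(m[node, 1L])
        b <- rec(m[node, 2L])
        out <- list()
        for (x in a) for (y in b) {
            out[[length(out) + 1L]] <- c(x, y)
            out[[length(out) + 1L]] <- c(y, x)
        }
        out
    }
    rec(nrow(m))
}

# objective of the leaf-ordering problem
adjacent_sum <- function(ord, d) {
    sum(vapply(seq_len(length(ord) - 1L),
               function(i) d[ord[i], ord[i + 1L]], 0))
}

# random symmetric dissimilarity matrix with zero diagonal
rand_dissim <- function(n) {
    v <- matrix(0, n, n)
    v[upper.tri(v)] <- runif(n * (n - 1) / 2, 0.05, 2)
    v <- v + t(v)
    labs <- sprintf("m%02d", seq_len(n))
    dimnames(v) <- list(labs, labs)
    new("DissimilarityMatrix", values = v)
}

# map a logo column data.frame to a named height vector (0 for absent)
column_heights <- function(df, symbols) {
    h <- setNames(rep(0, length(symbols)), symbols)
    if (nrow(df)) h[df$symbol] <- df$height
    h
}

svg_ns <- function(doc) {
    # work namespace-agnostically via local-name()
    doc
}
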