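# Built-in polygon letter shapes.
#
# Every glyph is a list of closed polygons (two-column matrices, x right,
# y up) inside the unit box (0,0)-(1,1). Letters are composed from
# rectangular and diagonal strokes; counters (the holes of A, B, O, ...)
# arise as negative space between strokes, so no explicit hole paths are
# needed. Polygon glyphs render identically on every system - no font
# metrics involved - which keeps SVG output byte-stable.

.g_rect <- function(x0, y0, x1, y1)
    cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))

# stroke of width w from p0 to p1
.g_diag <- function(x0, y0, x1, y1, w = 0.2) {
    dx <- x1 - x0; dy <- y1 - y0
    len <- sqrt(dx^2 + dy^2)
    nx <- -dy / len * w / 2; ny <- dx / len * w / 2
    cbind(c(x0 - nx, x0 + nx, x1 + nx, x1 - nx),
          c(y0 - ny, y0 + ny, y1 + ny, y1 - ny))
}

.buildGlyphs <- function() {
    w <- 0.2
    R <- .g_rect; D <- .g_diag
    g <- list(
        A = list(D(0.08, 0, 0.5, 1, 0.26), D(0.92, 0, 0.5, 1, 0.26),
                 R(0.25, 0.22, 0.75, 0.40)),
        B = list(R(0, 0, w, 1), R(0, 0.82, 0.88, 1), R(0, 0.42, 0.88, 0.60),
                 R(0, 0, 0.88, 0.18), R(0.72, 0.56, 0.92, 0.86),
                 R(0.76, 0.14, 0.96, 0.46)),
        C = list(R(0, 0, w, 1), R(0, 0.82, 0.96, 1), R(0, 0, 0.96, 0.18)),
        D = list(R(0, 0, w, 1), R(0, 0.82, 0.82, 1), R(0, 0, 0.82, 0.18),
                 R(0.78, 0.12, 0.98, 0.88)),
        E = list(R(0, 0, w, 1), R(0, 0.82, 0.94, 1), R(0, 0.41, 0.80, 0.59),
                 R(0, 0, 0.94, 0.18)),
        F = list(R(0, 0, w, 1), R(0, 0.82, 0.94, 1), R(0, 0.41, 0.80, 0.59)),
        G = list(R(0, 0, w, 1), R(0, 0.82, 0.96, 1), R(0, 0, 0.96, 0.18),
                 R(0.78, 0, 0.98, 0.48), R(0.52, 0.36, 0.98, 0.52)),
        H = list(R(0, 0, w, 1), R(0.8, 0, 1, 1), R(0, 0.41, 1, 0.59)),
        I = list(R(0.40, 0, 0.60, 1), R(0.08, 0.84, 0.92, 1),
                 R(0.08, 0, 0.92, 0.16)),
        J = list(R(0.68, 0.12, 0.88, 1), R(0.04, 0, 0.88, 0.18),
                 R(0.04, 0.10, 0.24, 0.40)),
        K = list(R(0, 0, w, 1), D(0.16, 0.52, 0.94, 1, 0.24),
                 D(0.16, 0.48, 0.94, 0, 0.24)),
        L = list(R(0, 0, w, 1), R(0, 0, 0.94, 0.18)),
        M = list(R(0, 0, w, 1), R(0.8, 0, 1, 1),
                 D(0.10, 1, 0.5, 0.38, 0.24), D(0.90, 1, 0.5, 0.38, 0.24)),
        N = list(R(0, 0, w, 1), R(0.8, 0, 1, 1), D(0.10, 1, 0.90, 0, 0.24)),
        O = list(R(0, 0, w, 1), R(0.8, 0, 1, 1), R(0, 0.82, 1, 1),
                 R(0, 0, 1, 0.18)),
        P = list(R(0, 0, w, 1), R(0, 0.82, 0.94, 1), R(0, 0.40, 0.94, 0.58),
                 R(0.76, 0.46, 0.96, 0.94)),
        Q = list(R(0, 0, w, 1), R(0.8, 0, 1, 1), R(0, 0.82, 1, 1),
                 R(0, 0, 1, 0.18), D(0.56, 0.42, 0.98, 0.02, 0.22)),
        R = list(R(0, 0, w, 1), R(0, 0.82, 0.94, 1), R(0, 0.40, 0.94, 0.58),
                 R(0.76, 0.46, 0.96, 0.94), D(0.42, 0.46, 0.96, 0, 0.24)),
        S = list(R(0, 0.82, 1, 1), R(0, 0.58, w, 0.90),
                 R(0, 0.41, 1, 0.59), R(0.8, 0.10, 1, 0.46),
                 R(0, 0, 1, 0.18)),
        T = list(R(0, 0.82, 1, 1), R(0.40, 0, 0.60, 1)),
        U = list(R(0, 0.12, w, 1), R(0.8, 0.12, 1, 1), R(0, 0, 1, 0.18)),
        V = list(D(0.06, 1, 0.5, 0, 0.26), D(0.94, 1, 0.5, 0, 0.26)),
        W = list(D(0.04, 1, 0.26, 0, 0.22), D(0.48, 0.70, 0.26, 0, 0.22),
                 D(0.52, 0.70, 0.74, 0, 0.22), D(0.96, 1, 0.74, 0, 0.22)),
        X = list(D(0.04, 1, 0.96, 0, 0.24), D(0.96, 1, 0.04, 0, 0.24)),
        Y = list(D(0.04, 1, 0.5, 0.46, 0.24), D(0.96, 1, 0.5, 0.46, 0.24),
                 R(0.40, 0, 0.60, 0.56)),
        Z = list(R(0, 0.82, 1, 1), R(0, 0, 1, 0.18),
                 D(0.90, 0.86, 0.10, 0.14, 0.24)))
    # diagonal stroke caps can overshoot; clamp everything to the unit box
    lapply(g, function(polys)
        lapply(polys, function(p) pmin(pmax(p, 0), 1)))
}

.GLYPHS <- .buildGlyphs()

#' Polygon glyph for a symbol
#'
#' Returns the list of closed polygons (two-column matrices inside the
#' unit box, y up) that draw the given symbol. Letters A-Z have built-in
#' shapes; any other symbol falls back to a rectangular ring.
#'
#' @param symbol single character.
#' @return list of polygon matrices.
#' @export
glyphPolygons <- function(symbol) {
    s <- toupper(symbol)
    g <- .GLYPHS[[s]]
    if (is.null(g))
        g <- list(.g_rect(0, 0, 0.2, 1), .g_rect(0.8, 0, 1, 1),
                  .g_rect(0, 0.82, 1, 1), .g_rect(0, 0, 1, 0.18))
    g
}
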