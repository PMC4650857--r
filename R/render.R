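#' Figure parameters
#'
#' @param width total canvas width in px; `NA` (default) derives it from
#'   the number of motif positions.
#' @param height canvas height in px.
#' @param pxPerPosition per-position column width in px (used when `width`
#'   is `NA`).
#' @param fontSize axis/label font size in px.
#' @param dpi resolution used for PNG output.
#' @param background canvas background color.
#' @return a [FigureSpec-class].
#' @export
figureSpec <- function(width = NA_real_, height = 260, pxPerPosition = 56,
                       fontSize = 12, dpi = 96, background = "white") {
    new("FigureSpec", width = as.numeric(width),
        height = as.numeric(height),
        pxPerPosition = as.numeric(pxPerPosition),
        fontSize = as.numeric(fontSize), dpi = as.numeric(dpi),
        background = background)
}

# ---- scene model -----------------------------------------------------------
# A scene is a list(width, height, ops) where ops are primitive drawing
# operations in SVG coordinates (y down). Two emitters consume scenes: a
# hand-written SVG 1.1 serializer (byte-deterministic, no timestamps) and a
# grDevices backend for PDF/PNG.

.op_rect <- function(x, y, w, h, fill, class = NULL, stroke = "none")
    list(type = "rect", x = x, y = y, w = w, h = h, fill = fill,
         class = class, stroke = stroke)

.op_line <- function(x1, y1, x2, y2, stroke = "#000000", width = 1,
                     class = NULL)
    list(type = "line", x1 = x1, y1 = y1, x2 = x2, y2 = y2,
         stroke = stroke, width = width, class = class)

.op_poly <- function(polys, fill, class = NULL)
    list(type = "poly", polys = polys, fill = fill, class = class)

.op_text <- function(x, y, str, size, anchor = "middle", rotate = 0,
                     class = NULL, fill = "#000000")
    list(type = "text", x = x, y = y, str = str, size = size,
         anchor = anchor, rotate = rotate, class = class, fill = fill)

.fmt <- function(x) sprintf("%.2f", x)

.xmlEscape <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
}

.emitSVG <- function(scene, path) {
    out <- c(sprintf(
        paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\"",
               " width=\"%s\" height=\"%s\" viewBox=\"0 0 %s %s\">"),
        .fmt(scene$width), .fmt(scene$height), .fmt(scene$width),
        .fmt(scene$height)))
    if (!is.null(scene$background))
        out <- c(out, sprintf(
            "<rect x=\"0\" y=\"0\" width=\"%s\" height=\"%s\" fill=\"%s\"/>",
            .fmt(scene$width), .fmt(scene$height), scene$background))
    cls <- function(op) if (is.null(op$class)) ""
                        else sprintf(" class=\"%s\"", op$class)
    for (op in scene$ops) {
        out <- c(out, switch(op$type,
            rect = sprintf(
                "<rect%s x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\" stroke=\"%s\"/>",
                cls(op), .fmt(op$x), .fmt(op$y), .fmt(op$w), .fmt(op$h),
                op$fill, op$stroke),
            line = sprintf(
                "<line%s x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"%s\" stroke-width=\"%s\"/>",
                cls(op), .fmt(op$x1), .fmt(op$y1), .fmt(op$x2),
                .fmt(op$y2), op$stroke, .fmt(op$width)),
            poly = {
                d <- paste(vapply(op$polys, function(p) {
                    pts <- paste(paste(.fmt(p[, 1]), .fmt(p[, 2]),
                                       sep = ","), collapse = " L ")
                    paste0("M ", pts, " Z")
                }, ""), collapse = " ")
                sprintf("<path%s d=\"%s\" fill=\"%s\" fill-rule=\"nonzero\"/>",
                        cls(op), d, op$fill)
            },
            text = {
                rot <- if (op$rotate != 0)
                    sprintf(" transform=\"rotate(%s %s %s)\"",
                            .fmt(op$rotate), .fmt(op$x), .fmt(op$y))
                else ""
                sprintf(
                    "<text%s x=\"%s\" y=\"%s\" font-family=\"sans-serif\" font-size=\"%s\" text-anchor=\"%s\" fill=\"%s\"%s>%s</text>",
                    cls(op), .fmt(op$x), .fmt(op$y), .fmt(op$size),
                    op$anchor, op$fill, rot, .xmlEscape(op$str))
            }))
    }
    out <- c(out, "</svg>")
    writeLines(out, path)
    invisible(path)
}

.emitDevice <- function(scene, path, spec) {
    ext <- tolower(tools::file_ext(path))
    if (ext == "pdf") {
        grDevices::pdf(path, width = scene$width / 72,
                       height = scene$height / 72)
    } else if (ext == "png") {
        grDevices::png(path, width = scene$width, height = scene$height,
                       res = spec@dpi, units = "px")
    } else {
        stop("unsupported output format '.", ext, "' (use svg, pdf or png)")
    }
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, scene$width),
                          ylim = c(scene$height, 0), xaxs = "i",
                          yaxs = "i")
    if (!is.null(scene$background))
        graphics::rect(0, scene$height, scene$width, 0,
                       col = scene$background, border = NA)
    for (op in scene$ops) {
        switch(op$type,
            rect = graphics::rect(op$x, op$y + op$h, op$x + op$w, op$y,
                col = op$fill,
                border = if (op$stroke == "none") NA else op$stroke),
            line = graphics::segments(op$x1, op$y1, op$x2, op$y2,
                col = op$stroke, lwd = op$width),
            poly = for (p in op$polys)
                graphics::polygon(p[, 1], p[, 2], col = op$fill,
                                  border = NA),
            text = graphics::text(op$x, op$y, op$str,
                adj = switch(op$anchor, start = 0, middle = 0.5, end = 1),
                cex = op$size / 12, srt = -op$rotate, col = op$fill))
    }
    invisible(path)
}

# Glyph polygons affine-mapped into the rectangle [x0, x0+w] x ordinate
# interval [lo, hi], in SVG coordinates given a value->y mapping.
.glyphOps <- function(symbol, x0, w, lo, hi, yOf, color) {
    polys <- lapply(glyphPolygons(symbol), function(p) {
        cbind(x0 + p[, 1] * w,
              yOf(lo + p[, 2] * (hi - lo)))
    })
    .op_poly(polys, fill = color, class = "glyph")
}

# Ops for the stacks of one logo inside a pixel rectangle.
.columnOps <- function(cols, px, py, pw, ph, ordMax, ordMin, colors,
                       padFrac = 0.08) {
    L <- length(cols@columns)
    cw <- pw / L
    yOf <- function(v) py + (ordMax - v) / (ordMax - ordMin) * ph
    ops <- list()
    for (l in seq_len(L)) {
        df <- cols@columns[[l]]
        if (!nrow(df)) next
        x0 <- px + (l - 1) * cw + padFrac * cw
        gw <- cw * (1 - 2 * padFrac)
        for (i in seq_len(nrow(df))) {
            lo <- min(df$base[i], df$base[i] + df$height[i])
            hi <- max(df$base[i], df$base[i] + df$height[i])
            ops[[length(ops) + 1L]] <-
                .glyphOps(df$symbol[i], x0, gw, lo, hi, yOf,
                          colors[[df$symbol[i]]])
        }
    }
    ops
}

.logoScene <- function(cols, spec, title = NULL) {
    L <- length(cols@columns)
    marL <- 46; marR <- 12; marB <- 38
    marT <- if (is.null(title)) 12 else 26
    width <- if (is.na(spec@width))
        marL + marR + L * spec@pxPerPosition else spec@width
    height <- spec@height
    pw <- width - marL - marR
    ph <- height - marT - marB
    ordMax <- cols@ordinateMax
    ordMin <- cols@ordinateMin
    yOf <- function(v) marT + (ordMax - v) / (ordMax - ordMin) * ph
    fs <- spec@fontSize
    ops <- list()
    # axes
    ops[[length(ops) + 1L]] <- .op_line(marL, marT, marL, marT + ph,
                                        class = "axis")
    ops[[length(ops) + 1L]] <- .op_line(marL, yOf(0), marL + pw, yOf(0),
                                        class = "baseline")
    yt <- pretty(c(ordMin, ordMax), 5)
    yt <- yt[yt >= ordMin - 1e-9 & yt <= ordMax + 1e-9]
    for (v in yt) {
        ops[[length(ops) + 1L]] <- .op_line(marL - 4, yOf(v), marL,
                                            yOf(v), class = "tick")
        ops[[length(ops) + 1L]] <- .op_text(marL - 6, yOf(v) + fs * 0.35,
            format(v), fs * 0.8, anchor = "end", class = "tick-label")
    }
    xstep <- max(1L, ceiling(L / 30))
    for (l in seq(1L, L, by = xstep)) {
        xc <- marL + (l - 0.5) * pw / L
        ops[[length(ops) + 1L]] <- .op_line(xc, marT + ph, xc,
                                            marT + ph + 4, class = "tick")
        ops[[length(ops) + 1L]] <- .op_text(xc, marT + ph + 4 + fs,
            as.character(l), fs * 0.8, class = "tick-label")
    }
    ops[[length(ops) + 1L]] <- .op_text(marL + pw / 2, height - 6,
        "position", fs, class = "axis-title")
    ops[[length(ops) + 1L]] <- .op_text(12, marT + ph / 2, "bits", fs,
        rotate = -90, class = "axis-title")
    if (!is.null(title))
        ops[[length(ops) + 1L]] <- .op_text(marL + pw / 2, fs + 4, title,
                                            fs, class = "title")
    ops <- c(ops, .columnOps(cols, marL, marT, pw, ph, ordMax, ordMin,
                             as.list(cols@alphabet@colors)))
    list(width = width, height = height, background = spec@background,
         ops = ops)
}

#' Render a logo to SVG, PDF or PNG
#'
#' Draws a sequence- or difference-logo geometry with 1-based position
#' ticks on the abscissa and bits on the ordinate; negative difference-logo
#' segments hang below a drawn zero line. The output format follows the
#' file extension. SVG output is fully deterministic (no timestamps, no
#' font dependence: glyphs are built-in polygons), so identical inputs
#' give byte-identical files.
#'
#' @param cols a [LogoColumns-class].
#' @param path output file ending in `.svg`, `.pdf` or `.png`.
#' @param spec a [FigureSpec-class].
#' @param title optional figure title.
#' @return invisibly, `path`.
#' @export
renderLogo <- function(cols, path, spec = figureSpec(), title = NULL) {
    stopifnot(is(cols, "LogoColumns"), is(spec, "FigureSpec"))
    scene <- .logoScene(cols, spec, title)
    if (tolower(tools::file_ext(path)) == "svg")
        .emitSVG(scene, path)
    else .emitDevice(scene, path, spec)
    invisible(path)
}

# positions of dendrogram nodes over the ordered leaves (x in cell units)
.dendrogramOps <- function(tree, ordering, x0, cw, top, bandH) {
    m <- tree$merge
    h <- tree$height
    leafX <- function(lab) x0 + (match(lab, ordering) - 0.5) * cw
    hmax <- max(h)
    yOf <- function(v) top + (1 - v / hmax) * (bandH - 4)
    nodeX <- numeric(nrow(m)); nodeY <- numeric(nrow(m))
    ops <- list()
    posOf <- function(node) {
        if (node < 0) c(leafX(tree$labels[-node]), top + bandH)
        else c(nodeX[node], nodeY[node])
    }
    for (i in seq_len(nrow(m))) {
        a <- posOf(m[i, 1L]); b <- posOf(m[i, 2L])
        y <- yOf(h[i])
        nodeX[i] <- (a[1L] + b[1L]) / 2
        nodeY[i] <- y
        ops[[length(ops) + 1L]] <- .op_line(a[1L], a[2L], a[1L], y,
                                            class = "dendro")
        ops[[length(ops) + 1L]] <- .op_line(b[1L], b[2L], b[1L], y,
                                            class = "dendro")
        ops[[length(ops) + 1L]] <- .op_line(a[1L], y, b[1L], y,
                                            class = "dendro")
    }
    ops
}

#' Render a comparison grid to SVG, PDF or PNG
#'
#' Draws the N x N difference-logo grid with an empty diagonal: per-cell
#' background rectangles in the grid's interpolated colors, a shared
#' ordinate across all cells, motif names above each column and left of
#' each row, and (optionally) the classic sequence logos and leaf-ordered
#' cluster tree above the columns.
#'
#' @param grid a [ComparisonGrid-class].
#' @param path output file ending in `.svg`, `.pdf` or `.png`.
#' @param spec a [FigureSpec-class] (height is taken per cell band).
#' @param headerLogos draw the sequence-logo header band.
#' @param dendrogram draw the cluster tree band.
#' @return invisibly, `path`.
#' @export
renderGrid <- function(grid, path, spec = figureSpec(),
                       headerLogos = TRUE, dendrogram = TRUE) {
    stopifnot(is(grid, "ComparisonGrid"), is(spec, "FigureSpec"))
    scene <- .gridScene(grid, spec, headerLogos, dendrogram)
    if (tolower(tools::file_ext(path)) == "svg")
        .emitSVG(scene, path)
    else .emitDevice(scene, path, spec)
    invisible(path)
}

.gridScene <- function(grid, spec, headerLogos, dendrogram) {
    n <- length(grid@motifs)
    L <- motifLength(grid@motifs[[1L]])
    fs <- spec@fontSize
    cw <- max(64, 10 * L)
    ch <- 64
    leftBand <- 86
    dendH <- if (dendrogram) 46 else 0
    headH <- if (headerLogos) 54 else 0
    nameH <- 18
    pad <- 10
    width <- leftBand + n * cw + pad
    height <- dendH + headH + nameH + n * ch + pad
    shared <- if (grid@sharedOrdinate > 0) grid@sharedOrdinate else 1
    colors <- as.list(grid@motifs[[1L]]@alphabet@colors)
    ops <- list()
    x0 <- leftBand
    if (dendrogram)
        ops <- c(ops, .dendrogramOps(grid@tree, grid@ordering, x0, cw, 4,
                                     dendH - 4))
    if (headerLogos) {
        for (j in seq_len(n)) {
            cols <- grid@headerLogos[[j]]
            ops <- c(ops, .columnOps(cols, x0 + (j - 1) * cw + 2,
                                     dendH + 2, cw - 4, headH - 4,
                                     cols@ordinateMax, 0, colors))
        }
    }
    for (j in seq_len(n))
        ops[[length(ops) + 1L]] <- .op_text(
            x0 + (j - 0.5) * cw, dendH + headH + nameH - 5,
            grid@ordering[j], fs * 0.85, class = "col-name")
    gridTop <- dendH + headH + nameH
    for (i in seq_len(n)) {
        ops[[length(ops) + 1L]] <- .op_text(
            leftBand - 6, gridTop + (i - 0.5) * ch + fs * 0.35,
            grid@ordering[i], fs * 0.85, anchor = "end",
            class = "row-name")
        for (j in seq_len(n)) {
            if (i == j) next
            cx <- x0 + (j - 1) * cw
            cy <- gridTop + (i - 1) * ch
            ops[[length(ops) + 1L]] <- .op_rect(cx, cy, cw, ch,
                fill = grid@cellColors[i, j], class = "cell-bg",
                stroke = "#FFFFFF")
            ops[[length(ops) + 1L]] <- .op_line(cx + 2, cy + ch / 2,
                cx + cw - 2, cy + ch / 2, stroke = "#666666",
                width = 0.5, class = "cell-zero")
            ops <- c(ops, .columnOps(grid@cells[[i]][[j]], cx + 2,
                                     cy + 2, cw - 4, ch - 4, shared,
                                     -shared, colors, padFrac = 0.05))
        }
    }
    list(width = width, height = height, background = spec@background,
         ops = ops)
}
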