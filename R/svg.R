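# Deterministic SVG emission. The body-map, histogram and heatmap documents
# are written directly (fixed element order, fixed 2-decimal coordinates) so
# identical inputs give byte-identical files and the structure -- e.g. one
# <polygon> per body segment -- is assertable with an XML parser.

.num <- function(x) sprintf("%.2f", x)

.svgOpen <- function(width, height) {
  c('<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d">'),
            width, height, width, height))
}

.svgText <- function(x, y, text, size = 10, anchor = "middle",
                     fill = "#000000") {
  sprintf(paste0('<text x="%s" y="%s" font-size="%d" font-family="sans-serif" ',
                 'text-anchor="%s" fill="%s">%s</text>'),
          .num(x), .num(y), size, anchor, fill, text)
}

.svgRect <- function(x, y, w, h, fill, stroke = "none") {
  sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s"/>',
          .num(x), .num(y), .num(w), .num(h), fill, stroke)
}

#' Built-in colour ramps
#'
#' "sequential" (light to dark, for counts and percentages), "diverging"
#' (centred for difference maps) and "heatmap" (dark to light so lighter
#' hues mean more frequent co-endorsement).
#'
#' @param name ramp name
#' @return character vector of colours, low to high
#' @examples
#' bodymapPalette("heatmap")
#' @export
bodymapPalette <- function(name = c("sequential", "diverging", "heatmap")) {
  switch(match.arg(name),
         sequential = c("#FFFFCC", "#FD8D3C", "#800026"),
         diverging = c("#2166AC", "#F7F7F7", "#B2182B"),
         heatmap = c("#000004", "#B63679", "#FCFDBF"))
}

#' Construct a rendering specification
#'
#' @param palette colour ramp, low to high (see [bodymapPalette()])
#' @param domain numeric(0) to derive the value domain from the data
#'   ([0, max] for nonnegative values, symmetric about 0 otherwise), or an
#'   explicit \code{c(lo, hi)}
#' @param labels draw three-digit code labels on segments
#' @param title document title ("" for none)
#' @return a \linkS4class{RenderSpec}
#' @export
renderSpec <- function(palette = bodymapPalette("sequential"),
                       domain = numeric(0), labels = FALSE, title = "") {
  new("RenderSpec", palette = palette, domain = domain, labels = labels,
      title = title)
}

.resolveDomain <- function(values, spec) {
  if (length(spec@domain) == 2L) return(spec@domain)
  values <- values[!is.na(values)]
  if (!length(values)) return(c(0, 1))
  if (any(values < 0)) {
    m <- max(abs(values))
    if (m == 0) m <- 1
    c(-m, m)
  } else {
    c(0, max(values, 1e-12))
  }
}

# map values through the ramp over the domain; NA -> grey
.mapColors <- function(values, spec) {
  dom <- .resolveDomain(values, spec)
  t <- (values - dom[1]) / (dom[2] - dom[1])
  t <- pmin(pmax(t, 0), 1)
  ramp <- colorRamp(spec@palette)
  out <- rep("#BDBDBD", length(values))
  ok <- !is.na(t)
  if (any(ok)) {
    m <- ramp(t[ok])
    out[ok] <- rgb(m[, 1], m[, 2], m[, 3], maxColorValue = 255)
  }
  out
}

.colorbar <- function(x, y, width, height, spec, dom, n = 40) {
  ramp <- colorRamp(spec@palette)
  ts <- (seq_len(n) - 0.5) / n
  cols <- rgb(ramp(ts), maxColorValue = 255)
  strips <- vapply(seq_len(n), function(i) {
    .svgRect(x + (i - 1) * width / n, y, width / n, height, cols[i])
  }, character(1))
  c(strips,
    .svgText(x, y + height + 12, .num(dom[1]), size = 9, anchor = "start"),
    .svgText(x + width, y + height + 12, .num(dom[2]), size = 9,
             anchor = "end"))
}

#' Render a body-map choropleth as an SVG document
#'
#' Draws the front (36 segments) and back (38 segments) panels side by
#' side, filling each segment's polygon by mapping its value through the
#' palette, with a colour bar and optional code labels. Output is
#' deterministic: identical inputs yield byte-identical documents, and the
#' document contains exactly one \code{<polygon>} element per segment.
#'
#' @param table a 74-row body-map table (columns id, group, value)
#' @param geometry a segment geometry from [cbmGeometry()]
#' @param spec a [renderSpec()]
#' @param file optional path to write the document to
#' @return the SVG document as a single character string, invisibly if
#'   \code{file} is given
#' @examples
#' svg <- renderBodyMap(aggregateMaps(workedExampleCohort()))
#' lengths(regmatches(svg, gregexpr("<polygon", svg)))
#' @export
renderBodyMap <- function(table, geometry = cbmGeometry(),
                          spec = renderSpec(), file = NULL) {
  .assertBodyMapTable(table)
  if (!is.numeric(table$value) || anyNA(table$value) && all(is.na(table$value)))
    stop("body-map values must be numeric", call. = FALSE)
  table <- table[order(table$id), ]
  dom <- .resolveDomain(table$value, spec)
  fills <- setNames(.mapColors(table$value, spec), table$id)

  width <- 840L; height <- 560L
  panelW <- 380; panelH <- 460; top <- 40
  panelX <- c(front = 20, back = 440)
  lines <- .svgOpen(width, height)
  if (nzchar(spec@title))
    lines <- c(lines, .svgText(width / 2, 20, spec@title, size = 14))
  for (panel in c("front", "back")) {
    lines <- c(lines, .svgText(panelX[[panel]] + panelW / 2, top - 6,
                               panel, size = 11))
    g <- geometry[geometry$panel == panel, ]
    for (code in sort(unique(g$code))) {
      v <- g[g$code == code, ]
      v <- v[order(v$vertex), ]
      px <- panelX[[panel]] + v$x * panelW
      py <- top + (1 - v$y) * panelH
      pts <- paste(paste0(.num(px), ",", .num(py)), collapse = " ")
      lines <- c(lines, sprintf(
        paste0('<polygon class="segment %s" data-code="%s" points="%s" ',
               'fill="%s" stroke="#333333" stroke-width="0.6"/>'),
        panel, code, pts, fills[[code]]))
    }
    if (spec@labels) {
      for (code in sort(unique(g$code))) {
        v <- g[g$code == code, ]
        lines <- c(lines, .svgText(panelX[[panel]] + mean(v$x) * panelW,
                                   top + (1 - mean(v$y)) * panelH + 2.5,
                                   code, size = 7))
      }
    }
  }
  lines <- c(lines, .colorbar(270, height - 40, 300, 14, spec, dom),
             "</svg>")
  doc <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

#' Render the endorsed-area count histogram as an SVG document
#'
#' One bar per bin of the per-patient endorsed-area counts; with the
#' default bin width of 1 each bar covers a single integer value, and bar
#' heights sum to the number of patients.
#'
#' @param counts nonnegative integer vector of per-patient endorsed-area
#'   counts (see [countEndorsed()])
#' @param binWidth bin width (>= 1, default 1)
#' @param title document title
#' @param file optional output path
#' @return the SVG document as a character string
#' @examples
#' renderNAreasHistogram(countEndorsed(workedExampleCohort())) -> svg
#' @export
renderNAreasHistogram <- function(counts, binWidth = 1, title = "",
                                  file = NULL) {
  if (!length(counts)) stop("no counts to plot", call. = FALSE)
  stopifnot(binWidth >= 1, all(counts >= 0))
  bin <- floor(counts / binWidth) * binWidth
  tab <- table(factor(bin, levels = seq(0, max(bin), by = binWidth)))
  width <- 640L; height <- 420L
  left <- 50; bottom <- height - 50; plotW <- width - 90; plotH <- 320
  barMax <- max(tab)
  nBins <- length(tab)
  bw <- plotW / nBins
  lines <- .svgOpen(width, height)
  if (nzchar(title)) lines <- c(lines, .svgText(width / 2, 20, title, 13))
  for (i in seq_len(nBins)) {
    h <- plotH * as.integer(tab[i]) / barMax
    if (h == 0) next
    lines <- c(lines, .svgRect(left + (i - 1) * bw + 0.5, bottom - h,
                               bw - 1, h, "#4292C6", stroke = "#08306B"))
  }
  ticks <- unique(round(seq(0, max(bin), length.out = min(nBins, 11))))
  for (t in ticks)
    lines <- c(lines, .svgText(left + (t / binWidth + 0.5) * bw, bottom + 14,
                               format(t), size = 9))
  lines <- c(lines,
             sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000"/>',
                     .num(left), .num(bottom), .num(left + plotW),
                     .num(bottom)),
             .svgText(width / 2, height - 12, "areas endorsed", size = 10),
             .svgText(16, bottom - plotH, format(barMax), size = 9,
                      anchor = "start"),
             "</svg>")
  doc <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

#' Render a co-occurrence heatmap as an SVG document
#'
#' A 74 x 74 cell grid with both axes in canonical code order. Cell colour
#' is a monotone function of the count, running dark to light so lighter
#' hues mark pairs more commonly endorsed together; the display is
#' symmetric because the underlying matrix is.
#'
#' @param x a \linkS4class{CooccurrenceMatrix}
#' @param spec a [renderSpec()]; default uses the dark-to-light "heatmap"
#'   ramp
#' @param file optional output path
#' @return the SVG document as a character string
#' @export
renderCooccurrenceHeatmap <- function(x,
                                      spec = renderSpec(
                                        palette = bodymapPalette("heatmap")),
                                      file = NULL) {
  m <- cooccurrenceCounts(x)
  cell <- 7; left <- 60; top <- 60
  width <- left + 74 * cell + 20
  height <- top + 74 * cell + 20
  cols <- matrix(.mapColors(as.vector(m), spec), 74, 74)
  lines <- .svgOpen(width, height)
  if (nzchar(spec@title)) lines <- c(lines, .svgText(width / 2, 20,
                                                     spec@title, 13))
  for (i in 1:74) for (j in 1:74) {
    lines <- c(lines, .svgRect(left + (j - 1) * cell,
                               top + (i - 1) * cell, cell, cell,
                               cols[i, j]))
  }
  every <- seq(1, 74, by = 8)
  for (k in every) {
    lines <- c(lines,
               .svgText(left + (k - 0.5) * cell, top - 6, rownames(m)[k], 8),
               .svgText(left - 6, top + (k - 0.5) * cell + 3, rownames(m)[k],
                        8, anchor = "end"))
  }
  lines <- c(lines, "</svg>")
  doc <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}
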