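#' Load a body-map segment geometry
#'
#' The packaged default is a schematic, synthetic polygon layout (one
#' simple, non-overlapping polygon per segment; 36 on the front panel, 38
#' on the back) honouring the segmentation logic of the instrument --
#' symmetric left/right segments with head, trunk and limbs in anatomical
#' order -- but not the licensed silhouette artwork, which is not
#' redistributable. A custom geometry CSV (columns code, panel, vertex, x,
#' y; normalized [0,1] coordinates per panel, y = 0 at the feet) can be
#' supplied by path. Anterior panels are drawn as the patient faces the
#' viewer, so the patient's right appears on the viewer's left; posterior
#' panels are drawn from behind.
#'
#' @param path optional geometry CSV path
#' @return data.frame with columns code, panel, vertex, x, y
#' @examples
#' g <- cbmGeometry()
#' length(unique(g$code))
#' @export
cbmGeometry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cbm_geometry_schematic.csv",
                        package = "bodymapr", mustWork = TRUE)
  g <- read.csv(path, colClasses = c(code = "character"))
  stopifnot(all(c("code", "panel", "vertex", "x", "y") %in% names(g)))
  codes <- sort(unique(g$code))
  if (!identical(codes, canonicalCodes()))
    stop("geometry must cover exactly the 74 canonical codes", call. = FALSE)
  pan <- unique(g[, c("code", "panel")])
  if (nrow(pan) != 74L || !identical(pan$panel[order(pan$code)],
                                     sideOf(sort(pan$code))))
    stop("geometry panel assignment inconsistent with code sides",
         call. = FALSE)
  if (any(g$x < 0 | g$x > 1 | g$y < 0 | g$y > 1))
    stop("geometry coordinates must be normalized to [0, 1]", call. = FALSE)
  if (any(table(g$code) < 3L))
    stop("each segment needs at least 3 vertices", call. = FALSE)
  g
}

#' Body-map choropleth as a ggplot
#'
#' The grammar-of-graphics counterpart of [renderBodyMap()]: front and back
#' panels as facets, one filled polygon per segment. Returned objects can
#' be customised with further ggplot2 layers; use [renderBodyMap()] when a
#' deterministic standalone SVG document is needed.
#'
#' @param table a 74-row body-map table (columns id, group, value)
#' @param geometry a [cbmGeometry()]
#' @param palette colour ramp for the fill scale
#' @param title plot title
#' @param labels draw code labels at segment centres
#' @return a ggplot object
#' @examples
#' p <- plotBodyMap(aggregateMaps(workedExampleCohort()))
#' @export
plotBodyMap <- function(table, geometry = cbmGeometry(),
                        palette = bodymapPalette("sequential"),
                        title = NULL, labels = FALSE) {
  .assertBodyMapTable(table)
  df <- merge(geometry, table[, c("id", "value")],
              by.x = "code", by.y = "id")
  df$panel <- factor(df$panel, levels = c("front", "back"))
  df <- df[order(df$code, df$vertex), ]
  if (any(table$value < 0, na.rm = TRUE) &&
      missing(palette)) palette <- bodymapPalette("diverging")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        group = .data$code,
                                        fill = .data$value)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.25) +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel)) +
    ggplot2::scale_fill_gradientn(colours = palette, na.value = "grey70") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "right")
  if (labels) {
    anchors <- do.call(rbind, lapply(split(df, df$code), function(d) {
      data.frame(code = d$code[1], panel = d$panel[1],
                 x = mean(d$x), y = mean(d$y))
    }))
    p <- p + ggplot2::geom_text(
      data = anchors,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$code),
      inherit.aes = FALSE, size = 2)
  }
  if (!is.null(title)) p <- p + ggplot2::ggtitle(title)
  p
}

#' Histogram of endorsed-area counts as a ggplot
#'
#' @param x a \linkS4class{BodyMapCohort}, a character vector of
#'   endorsement strings, or a numeric vector of per-patient counts
#' @param binwidth histogram bin width (default 1: one bar per value)
#' @return a ggplot object
#' @examples
#' p <- plotNAreasHistogram(workedExampleCohort())
#' @export
plotNAreasHistogram <- function(x, binwidth = 1) {
  counts <- if (is(x, "BodyMapCohort")) countEndorsed(x)
            else if (is.character(x)) countEndorsed(x)
            else x
  if (!length(counts)) stop("no counts to plot", call. = FALSE)
  ggplot2::ggplot(data.frame(n_areas = counts),
                  ggplot2::aes(x = .data$n_areas)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = -0.5,
                            fill = "#4292C6", colour = "#08306B") +
    ggplot2::labs(x = "areas endorsed", y = "patients") +
    ggplot2::theme_minimal()
}

#' Co-occurrence heatmap as a ggplot
#'
#' @param x a \linkS4class{CooccurrenceMatrix}
#' @param palette colour ramp (default dark-to-light, lighter = more
#'   co-endorsed)
#' @return a ggplot object
#' @examples
#' p <- plotCooccurrence(cooccurrenceMatrix(workedExampleCohort()))
#' @export
plotCooccurrence <- function(x, palette = bodymapPalette("heatmap")) {
  m <- cooccurrenceCounts(x)
  df <- data.frame(code1 = rep(rownames(m), times = 74),
                   code2 = rep(colnames(m), each = 74),
                   count = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$code2, y = .data$code1,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(colours = palette) +
    ggplot2::scale_y_discrete(limits = rev(rownames(m))) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_text(size = 4),
                   axis.text.x = ggplot2::element_text(angle = 90))
}
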