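test_that("the schematic geometry covers the 74 segments consistently", {
  g <- cbmGeometry()
  expect_identical(sort(unique(g$code)), canonicalCodes())
  pan <- unique(g[, c("code", "panel")])
  expect_identical(sum(pan$panel == "front"), 36L)
  expect_identical(sum(pan$panel == "back"), 38L)
  expect_identical(pan$panel[order(pan$code)], sideOf(sort(pan$code)))
  expect_true(all(g$x >= 0 & g$x <= 1 & g$y >= 0 & g$y <= 1))
  expect_true(all(table(g$code) >= 3))

  # polygons within a panel have pairwise disjoint interiors (rectangles:
  # bounding-box test is exact)
  for (panel in c("front", "back")) {
    boxes <- do.call(rbind, lapply(split(g[g$panel == panel, ],
                                         g$code[g$panel == panel]),
      function(d) data.frame(x0 = min(d$x), x1 = max(d$x),
                             y0 = min(d$y), y1 = max(d$y))))
    n <- nrow(boxes)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      xo <- min(boxes$x1[i], boxes$x1[j]) - max(boxes$x0[i], boxes$x0[j])
      yo <- min(boxes$y1[i], boxes$y1[j]) - max(boxes$y0[i], boxes$y0[j])
      expect_false(xo > 1e-9 && yo > 1e-9)
    }
  }
})

test_that("body-map SVG has one filled polygon per segment, 36/38 by panel", {
  skip_if_not_installed("xml2")
  svg <- renderBodyMap(aggregateMaps(workedExampleCohort()),
                       spec = renderSpec(labels = TRUE, title = "example"))
  doc <- xml2::read_xml(svg)
  polys <- xml2::xml_find_all(doc, "//*[local-name() = 'polygon']")
  expect_identical(length(polys), 74L)
  cls <- xml2::xml_attr(polys, "class")
  expect_identical(sum(grepl("front", cls)), 36L)
  expect_identical(sum(grepl("back", cls)), 38L)
  fills <- xml2::xml_attr(polys, "fill")
  expect_true(all(grepl("^#[0-9A-Fa-f]{6}$", fills)))
  expect_setequal(xml2::xml_attr(polys, "data-code"), canonicalCodes())
})

test_that("rendering is deterministic and constant maps are one colour", {
  tab <- aggregateMaps(workedExampleCohort())
  expect_identical(renderBodyMap(tab), renderBodyMap(tab))
  f1 <- tempfile(fileext = ".svg"); f2 <- tempfile(fileext = ".svg")
  renderBodyMap(tab, file = f1); renderBodyMap(tab, file = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  const <- bodyMapTable(fill = 3)
  svg <- renderBodyMap(const)
  fills <- regmatches(svg, gregexpr('polygon[^>]*fill="(#[0-9A-F]{6})"',
                                    svg))[[1]]
  expect_identical(length(unique(sub('.*fill="', "", fills))), 1L)
})

test_that("tables missing a segment are rejected naming the code", {
  tab <- aggregateMaps(workedExampleCohort())
  expect_error(renderBodyMap(tab[tab$id != "218", ]), "218")
  tab2 <- tab
  tab2$value <- as.character(tab2$value)
  expect_error(renderBodyMap(tab2), "numeric")
})

test_that("colour mapping is monotone in value", {
  spec <- renderSpec(domain = c(0, 10))
  cols <- bodymapr:::.mapColors(c(0, 2, 5, 7, 10), spec)
  ramp <- colorRamp(spec@palette)
  expected <- rgb(ramp(c(0, .2, .5, .7, 1)), maxColorValue = 255)
  expect_identical(cols, expected)
  # NA (degenerate) values fall back to grey
  expect_identical(bodymapr:::.mapColors(c(NA, 1), spec)[1], "#BDBDBD")
})

test_that("difference maps get a symmetric automatic domain", {
  d <- differenceMap(bodyMapTable(c("218" = 30)), bodyMapTable(c("101" = 10)))
  expect_identical(bodymapr:::.resolveDomain(d$value, renderSpec()),
                   c(-30, 30))
  expect_identical(bodymapr:::.resolveDomain(c(0, 5), renderSpec()), c(0, 5))
})

test_that("area-count histogram bars mirror the tally", {
  svg <- renderNAreasHistogram(countEndorsed(workedExampleCohort()))
  bars <- regmatches(svg, gregexpr('<rect [^>]*stroke="#08306B"', svg))[[1]]
  expect_identical(length(bars), 2L)       # one bar at 4, one at 6
  # all patients identical: a single bar
  svg1 <- renderNAreasHistogram(rep(5L, 10))
  bars1 <- regmatches(svg1, gregexpr('<rect [^>]*stroke="#08306B"', svg1))[[1]]
  expect_identical(length(bars1), 1L)
  expect_error(renderNAreasHistogram(integer(0)), "no counts")
  expect_identical(renderNAreasHistogram(c(1, 3, 3)),
                   renderNAreasHistogram(c(1, 3, 3)))
})

test_that("co-occurrence heatmap is symmetric with lighter = more frequent", {
  cm <- cooccurrenceMatrix(workedExampleCohort())
  svg <- renderCooccurrenceHeatmap(cm)
  fills <- sub('"$', "",
               sub('.*fill="', "",
                   regmatches(svg, gregexpr('<rect [^>]*fill="#[0-9A-F]{6}"',
                                            svg))[[1]]))
  expect_identical(length(fills), 74L * 74L)
  cellFill <- function(i, j) fills[(i - 1) * 74 + j]
  luminance <- function(hex) {
    v <- col2rgb(hex)
    sum(v * c(0.299, 0.587, 0.114))
  }
  # (101,102) counted twice, (101,103) once: the former must be lighter
  expect_gt(luminance(cellFill(1, 2)), luminance(cellFill(1, 3)))
  # symmetric display
  expect_identical(cellFill(1, 2), cellFill(2, 1))
  expect_identical(cellFill(1, 3), cellFill(3, 1))
  expect_identical(renderCooccurrenceHeatmap(cm),
                   renderCooccurrenceHeatmap(cm))
})

test_that("ggplot front-ends return customisable plot objects", {
  expect_s3_class(plotBodyMap(aggregateMaps(workedExampleCohort()),
                              labels = TRUE), "ggplot")
  expect_s3_class(plotNAreasHistogram(workedExampleCohort()), "ggplot")
  expect_s3_class(plotNAreasHistogram(c(1, 2, 2, 5)), "ggplot")
  expect_s3_class(plotCooccurrence(cooccurrenceMatrix(workedExampleCohort())),
                  "ggplot")
})
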