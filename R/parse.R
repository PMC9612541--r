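#' Construct a parsing policy for endorsement strings
#'
#' @param delimiter single character to split on (default ",")
#' @param duplicates "dedupe" (collapse repeats with a warning) or "error"
#' @param unknown "error" (abort on a non-canonical token) or "drop"
#'   (discard it with a warning)
#' @return a \linkS4class{ParsePolicy}
#' @examples
#' parseEndorsement("101;102", parsePolicy(delimiter = ";"))
#' @export
parsePolicy <- function(delimiter = ",", duplicates = c("dedupe", "error"),
                        unknown = c("error", "drop")) {
  new("ParsePolicy", delimiter = delimiter,
      duplicates = match.arg(duplicates), unknown = match.arg(unknown))
}

#' Parse one delimited endorsement string into a set of segment codes
#'
#' Splits on the policy delimiter, trims whitespace around each token, and
#' validates every token against the canonical 74-code set. An empty string
#' (a patient endorsing no locations) parses to an empty set.
#'
#' @param s a single character string, e.g. \code{"101, 102, 201, 202"}
#' @param policy a [parsePolicy()]
#' @return character vector of distinct canonical codes, sorted ascending
#' @examples
#' parseEndorsement("101, 102, 201, 202")
#' parseEndorsement("")
#' @export
parseEndorsement <- function(s, policy = parsePolicy()) {
  stopifnot(is.character(s), length(s) == 1L)
  if (is.na(s)) s <- ""
  tokens <- trimws(strsplit(s, policy@delimiter, fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) return(character(0))
  bad <- which(!tokens %in% canonicalCodes())
  if (length(bad)) {
    msg <- paste(sprintf("'%s' (position %d)", tokens[bad], bad),
                 collapse = ", ")
    if (policy@unknown == "error")
      stop("unknown segment code token: ", msg, call. = FALSE)
    warning("dropping unknown segment code token: ", msg, call. = FALSE)
    tokens <- tokens[-bad]
  }
  if (anyDuplicated(tokens)) {
    dup <- unique(tokens[duplicated(tokens)])
    if (policy@duplicates == "error")
      stop("duplicated segment codes in endorsement string: ",
           paste0("'", dup, "'", collapse = ", "), call. = FALSE)
    warning("deduplicating repeated segment codes: ",
            paste0("'", dup, "'", collapse = ", "), call. = FALSE)
    tokens <- unique(tokens)
  }
  sort(tokens)
}

# validate the (id, group, value) body-map table contract
.assertBodyMapTable <- function(table, binary = FALSE) {
  if (!is.data.frame(table) ||
      !all(c("id", "group", "value") %in% names(table)))
    stop("a body-map table needs columns id, group, value", call. = FALSE)
  codes <- canonicalCodes()
  missing <- setdiff(codes, table$id)
  extra <- setdiff(table$id, codes)
  if (length(missing) || length(extra) || nrow(table) != 74L)
    stop("body-map table must have one row per canonical code",
         if (length(missing)) paste0("; missing: ",
                                     paste0("'", missing, "'", collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ",
                                   paste0("'", extra, "'", collapse = ", ")),
         call. = FALSE)
  if (!identical(as.character(table$group), sideOf(table$id)))
    stop("body-map table 'group' column inconsistent with code sides",
         call. = FALSE)
  if (!is.numeric(table$value))
    stop("body-map table 'value' column must be numeric", call. = FALSE)
  if (binary && !all(table$value %in% c(0, 1)))
    stop("single-patient body-map values must be 0/1", call. = FALSE)
  invisible(table)
}

#' Build a body-map table from per-code values
#'
#' The body-map table is the package's plotting and aggregation currency: a
#' data.frame with exactly 74 rows and columns \code{id} (segment code),
#' \code{group} ("front"/"back") and \code{value}, sorted by code.
#'
#' @param values numeric vector named by canonical code; codes not named
#'   get \code{fill}
#' @param fill default value for unnamed codes (default 0)
#' @return a body-map table
#' @examples
#' tab <- bodyMapTable(c("218" = 25, "219" = 20))
#' tab[tab$value > 0, ]
#' @export
bodyMapTable <- function(values = numeric(0), fill = 0) {
  codes <- canonicalCodes()
  if (length(values)) {
    stopifnot(!is.null(names(values)))
    sideOf(names(values)) # validates codes
  }
  v <- rep(fill, 74)
  names(v) <- codes
  v[names(values)] <- values
  data.frame(id = codes, group = sideOf(codes), value = unname(v),
             stringsAsFactors = FALSE)
}

#' Expand one endorsement string to a binary body-map table
#'
#' Produces the full 74-row table with value 1 at each endorsed code and 0
#' elsewhere -- the single-patient body map ready for aggregation or
#' plotting.
#'
#' @inheritParams parseEndorsement
#' @return a binary body-map table (74 rows)
#' @examples
#' tab <- stringToMap("101, 102, 201, 202")
#' sum(tab$value)
#' @export
stringToMap <- function(s, policy = parsePolicy()) {
  codes <- parseEndorsement(s, policy)
  bodyMapTable(setNames(rep(1, length(codes)), codes))
}

#' Sum endorsement across a collection of body maps
#'
#' Adds the per-segment values of the input maps elementwise, producing the
#' per-segment raw endorsement count across patients.
#'
#' @param maps a list of body-map tables on the same 74-code schema, or a
#'   \linkS4class{BodyMapCohort}
#' @return a body-map table of per-code sums
#' @examples
#' maps <- lapply(c("101, 102", "101, 218"), stringToMap)
#' agg <- aggregateMaps(maps)
#' agg$value[agg$id == "101"]
#' @export
setGeneric("aggregateMaps", function(maps) standardGeneric("aggregateMaps"))

#' @rdname aggregateMaps
#' @export
setMethod("aggregateMaps", "list", function(maps) {
  if (!length(maps)) stop("no maps to aggregate", call. = FALSE)
  total <- rep(0, 74)
  for (m in maps) {
    .assertBodyMapTable(m)
    m <- m[order(m$id), ]
    total <- total + m$value
  }
  bodyMapTable(setNames(total, canonicalCodes()))
})

#' @rdname aggregateMaps
#' @export
setMethod("aggregateMaps", "BodyMapCohort", function(maps) {
  bodyMapTable(rowSums(endorsedMatrix(maps)))
})

#' Convert per-segment counts to percent endorsement
#'
#' @param counts a body-map table of nonnegative counts (each <= n)
#' @param n number of patients the counts were tallied over (>= 1)
#' @return a body-map table of percentages in [0, 100]
#' @examples
#' pct <- percentMap(bodyMapTable(c("101" = 1)), n = 4)
#' pct$value[pct$id == "101"]
#' @export
percentMap <- function(counts, n) {
  .assertBodyMapTable(counts)
  if (length(n) != 1L || !is.numeric(n) || n < 1)
    stop("n must be a single patient count >= 1", call. = FALSE)
  if (any(counts$value < 0) || any(counts$value > n))
    stop("counts must lie in [0, n]", call. = FALSE)
  counts$value <- 100 * counts$value / n
  counts
}

#' Number of distinct areas endorsed
#'
#' The per-patient endorsed-area count underlying the area-count histogram.
#'
#' @param x a character vector of endorsement strings, or a
#'   \linkS4class{BodyMapCohort}
#' @param policy a [parsePolicy()] (string method)
#' @return integer vector of per-patient counts
#' @examples
#' countEndorsed(c("101, 102, 103, 104, 201, 202", ""))
#' @export
setGeneric("countEndorsed", function(x, ...) standardGeneric("countEndorsed"))

#' @rdname countEndorsed
#' @export
setMethod("countEndorsed", "character", function(x, policy = parsePolicy()) {
  vapply(x, function(s) length(parseEndorsement(s, policy)), integer(1),
         USE.NAMES = FALSE)
})

#' @rdname countEndorsed
#' @export
setMethod("countEndorsed", "BodyMapCohort", function(x) {
  as.integer(unname(colSums(endorsedMatrix(x))))
})

#' Write a body-map table to CSV
#'
#' Columns id, group, value, one row per canonical code, sorted by code so
#' output files diff deterministically.
#'
#' @param table a body-map table
#' @param path output file path
#' @return the path, invisibly
#' @export
writeBodyMapTable <- function(table, path) {
  .assertBodyMapTable(table)
  table <- table[order(table$id), ]
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
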