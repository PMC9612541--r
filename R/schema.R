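#' The 74 canonical body-map segment codes
#'
#' Three-digit codes "101".."136" (front of body, 36 segments) and
#' "201".."238" (back of body, 38 segments), in ascending order. All tables
#' and matrices in the package are indexed by this fixed code set.
#'
#' @return character vector of length 74
#' @examples
#' length(canonicalCodes())
#' @export
canonicalCodes <- function() {
  c(sprintf("1%02d", 1:36), sprintf("2%02d", 1:38))
}

.schemaPath <- function() {
  system.file("extdata", "cbm_schema.csv", package = "bodymapr",
              mustWork = TRUE)
}

#' Canonical body-map schema
#'
#' The registry of the 74 segments: code, side (front/back) and anatomical
#' label. The male and female silhouettes share one unified code space here;
#' silhouette-specific code systems are handled by [convertMap()] with a
#' user-supplied [readCodeMapping()] asset.
#'
#' @param variant silhouette identifier, "male" or "female"
#' @param path optional path to an alternative schema CSV
#'   (columns code, side, label)
#' @return data.frame with 74 rows and columns code, side, label
#' @examples
#' sch <- canonicalSchema("male")
#' table(sch$side)
#' sch$label[sch$code == "218"]
#' @export
canonicalSchema <- function(variant = c("male", "female"), path = NULL) {
  if (length(variant) == 1L && !variant %in% c("male", "female"))
    stop("unknown body-map variant: '", variant, "'", call. = FALSE)
  variant <- match.arg(variant)
  key <- if (is.null(path)) "schema" else paste0("schema:", path)
  if (is.null(.bodymapr_cache[[key]])) {
    sch <- read.csv(if (is.null(path)) .schemaPath() else path,
                    colClasses = "character")
    stopifnot(all(c("code", "side", "label") %in% names(sch)))
    sch <- sch[order(sch$code), , drop = FALSE]
    rownames(sch) <- NULL
    if (nrow(sch) != 74L || anyDuplicated(sch$code))
      stop("schema must have exactly 74 distinct codes", call. = FALSE)
    if (!identical(sch$code, canonicalCodes()))
      stop("schema codes must be the canonical 74", call. = FALSE)
    if (sum(sch$side == "front") != 36L || sum(sch$side == "back") != 38L)
      stop("schema must have 36 front and 38 back entries", call. = FALSE)
    if (!identical(sch$side, sideOf(sch$code)))
      stop("schema side column inconsistent with code leading digit",
           call. = FALSE)
    .bodymapr_cache[[key]] <- sch
  }
  .bodymapr_cache[[key]]
}

#' Side of the body a segment code lies on
#'
#' Codes beginning with "1" are on the front of the body, codes beginning
#' with "2" on the back.
#'
#' @param code character vector of canonical segment codes
#' @return character vector, "front" or "back"
#' @examples
#' sideOf(c("101", "238"))
#' @export
sideOf <- function(code) {
  bad <- setdiff(code, canonicalCodes())
  if (length(bad))
    stop("not a canonical segment code: ",
         paste0("'", bad, "'", collapse = ", "), call. = FALSE)
  ifelse(substr(code, 1, 1) == "1", "front", "back")
}

#' Anatomical label of a segment code
#'
#' @param code character vector of canonical segment codes
#' @param variant silhouette variant passed to [canonicalSchema()]
#' @return character vector of anatomical descriptions
#' @examples
#' segmentLabel("218")
#' @export
segmentLabel <- function(code, variant = "male") {
  sch <- canonicalSchema(variant)
  sideOf(code) # validates
  sch$label[match(code, sch$code)]
}

#' Read a code-mapping asset
#'
#' A mapping is a total, side-preserving bijection between two 74-code
#' spaces, stored as a CSV with columns \code{from} and \code{to}. The
#' packaged default is the identity mapping (the unified code space used for
#' all computation); a silhouette-specific correspondence table can be
#' supplied by path.
#'
#' @param path CSV path; default: the packaged identity mapping
#' @return data.frame with columns from, to (74 rows)
#' @examples
#' m <- readCodeMapping()
#' identical(m$from, m$to)
#' @export
readCodeMapping <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cbm_mapping_identity.csv",
                        package = "bodymapr", mustWork = TRUE)
  map <- read.csv(path, colClasses = "character")
  stopifnot(all(c("from", "to") %in% names(map)))
  if (nrow(map) != 74L ||
      anyDuplicated(map$from) || anyDuplicated(map$to) ||
      !setequal(map$from, canonicalCodes()) ||
      !setequal(map$to, canonicalCodes()))
    stop("mapping must be a bijection covering all 74 codes", call. = FALSE)
  if (!identical(sideOf(map$from), sideOf(map$to)))
    stop("mapping must be side-preserving", call. = FALSE)
  map[order(map$from), , drop = FALSE]
}

#' Re-code a body-map table under a code mapping
#'
#' Carries the value of each segment over to its image code, leaving values
#' unchanged. Used to move between silhouette-specific code systems.
#'
#' @param table a 74-row body-map table (columns id, group, value)
#' @param mapping a mapping data.frame from [readCodeMapping()]
#' @return a body-map table on the mapped codes, sorted by code
#' @examples
#' tab <- stringToMap("101, 218")
#' identical(convertMap(tab, readCodeMapping()), tab)
#' @export
convertMap <- function(table, mapping = readCodeMapping()) {
  .assertBodyMapTable(table)
  unmapped <- setdiff(table$id, mapping$from)
  if (length(unmapped))
    stop("mapping is missing codes present in the table: ",
         paste0("'", unmapped, "'", collapse = ", "), call. = FALSE)
  out <- table
  out$id <- mapping$to[match(table$id, mapping$from)]
  out$group <- sideOf(out$id)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname convertMap
#' @param tables a list of body-map tables, all converted under the same
#'   mapping
#' @export
convertMaps <- function(tables, mapping = readCodeMapping()) {
  stopifnot(is.list(tables))
  lapply(tables, convertMap, mapping = mapping)
}
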