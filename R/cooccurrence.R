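#' Pairwise co-occurrence of segment endorsement
#'
#' Counts, for every unordered pair of segments, the number of patients
#' whose body map endorses both -- each patient contributes at most once to
#' each pair. With E the 74 x n binary endorsement matrix the count matrix
#' is E E' with its diagonal zeroed, so the off-diagonal cell space has
#' 74 x 73 = 5402 cells (each unordered pair appearing twice by symmetry).
#'
#' @param x a \linkS4class{BodyMapCohort}, or a character vector of
#'   delimited endorsement strings
#' @param ... passed to methods (the character method accepts
#'   \code{policy})
#' @return a \linkS4class{CooccurrenceMatrix}
#' @examples
#' cm <- cooccurrenceMatrix(workedExampleCohort())
#' cooccurrenceCounts(cm)["101", c("102", "103")]
#' @export
setGeneric("cooccurrenceMatrix",
           function(x, ...) standardGeneric("cooccurrenceMatrix"))

#' @rdname cooccurrenceMatrix
#' @export
setMethod("cooccurrenceMatrix", "BodyMapCohort", function(x) {
  e <- endorsedMatrix(x)
  counts <- e %*% t(e)
  diag(counts) <- 0L
  storage.mode(counts) <- "integer"
  new("CooccurrenceMatrix", counts = counts)
})

#' @rdname cooccurrenceMatrix
#' @export
setMethod("cooccurrenceMatrix", "character",
          function(x, policy = parsePolicy()) {
  cooccurrenceMatrix(BodyMapCohort(x, policy = policy))
})

#' Counts of a co-occurrence matrix
#'
#' @param x a \linkS4class{CooccurrenceMatrix}
#' @return the 74 x 74 integer count matrix
#' @export
cooccurrenceCounts <- function(x) {
  stopifnot(is(x, "CooccurrenceMatrix"))
  x@counts
}

setMethod("show", "CooccurrenceMatrix", function(object) {
  m <- object@counts
  nz <- sum(m[upper.tri(m)] > 0)
  cat(sprintf(paste0("CooccurrenceMatrix: 74 x 74 (%d off-diagonal cells), ",
                     "%d co-endorsed pairs, max count %d\n"),
              74L * 73L, nz, max(m)))
})

#' Most co-endorsed segment pairs
#'
#' Unordered pairs ranked by co-occurrence count (descending), ties broken
#' by first then second code ascending; pairs never co-endorsed are
#' excluded.
#'
#' @param x a \linkS4class{CooccurrenceMatrix}
#' @param k maximum number of pairs to return (>= 1); if fewer pairs have
#'   nonzero counts, all of them are returned
#' @return data.frame with columns code1, code2, label1, label2, count
#' @examples
#' topCooccurring(cooccurrenceMatrix(workedExampleCohort()), k = 3)
#' @export
topCooccurring <- function(x, k = 10) {
  stopifnot(is(x, "CooccurrenceMatrix"), k >= 1)
  m <- cooccurrenceCounts(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  out <- data.frame(
    code1 = rownames(m)[idx[, 1]], code2 = colnames(m)[idx[, 2]],
    count = m[idx], stringsAsFactors = FALSE
  )
  out <- out[out$count > 0, , drop = FALSE]
  out <- out[order(-out$count, out$code1, out$code2), , drop = FALSE]
  out <- utils::head(out, k)
  out$label1 <- segmentLabel(out$code1)
  out$label2 <- segmentLabel(out$code2)
  rownames(out) <- NULL
  out[, c("code1", "code2", "label1", "label2", "count")]
}

#' Long-format view of a co-occurrence matrix
#'
#' One row per unordered pair (code1 < code2), including zero counts, for
#' CSV export.
#'
#' @param x a \linkS4class{CooccurrenceMatrix}
#' @return data.frame with columns code1, code2, count (2701 rows)
#' @export
cooccurrenceLong <- function(x) {
  m <- cooccurrenceCounts(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  out <- data.frame(
    code1 = rownames(m)[idx[, 1]], code2 = colnames(m)[idx[, 2]],
    count = m[idx], stringsAsFactors = FALSE
  )
  out <- out[order(out$code1, out$code2), ]
  rownames(out) <- NULL
  out
}

#' Write a co-occurrence matrix to CSV
#'
#' Writes both layouts the field exchanges: a long-format pair list
#' (\code{<path>}) and, optionally, the square matrix with code dimnames.
#'
#' @param x a \linkS4class{CooccurrenceMatrix}
#' @param path output CSV path for the long format
#' @param matrixPath optional output CSV path for the square matrix
#' @return \code{path}, invisibly
#' @export
writeCooccurrence <- function(x, path, matrixPath = NULL) {
  write.csv(cooccurrenceLong(x), path, row.names = FALSE, quote = FALSE)
  if (!is.null(matrixPath))
    write.csv(data.frame(code = rownames(cooccurrenceCounts(x)),
                         cooccurrenceCounts(x), check.names = FALSE),
              matrixPath, row.names = FALSE, quote = FALSE)
  invisible(path)
}
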