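#' Build a BodyMapCohort from endorsement strings
#'
#' Parses one delimited endorsement string per patient into the 74 x n
#' binary endorsement matrix and attaches covariates as \code{colData}.
#'
#' @param endorsement character vector, one delimited code string per patient
#' @param patientId unique patient identifiers (default "P1".."Pn")
#' @param covariates optional data.frame of per-patient covariates (group
#'   labels, numeric scores), one row per patient
#' @param policy a [parsePolicy()]
#' @return a \linkS4class{BodyMapCohort}
#' @examples
#' bmc <- BodyMapCohort(c("101, 102, 103, 104, 201, 202", "101, 102, 201, 202"))
#' countEndorsed(bmc)
#' @export
BodyMapCohort <- function(endorsement, patientId = NULL, covariates = NULL,
                          policy = parsePolicy()) {
  stopifnot(is.character(endorsement))
  n <- length(endorsement)
  if (is.null(patientId)) patientId <- sprintf("P%d", seq_len(n))
  patientId <- as.character(patientId)
  if (length(patientId) != n)
    stop("patientId must match the number of endorsement strings",
         call. = FALSE)
  if (anyDuplicated(patientId))
    stop("patient identifiers must be unique", call. = FALSE)
  codes <- canonicalCodes()
  mat <- matrix(0L, nrow = 74L, ncol = n, dimnames = list(codes, patientId))
  for (i in seq_len(n)) {
    endorsed <- parseEndorsement(endorsement[i], policy)
    mat[endorsed, i] <- 1L
  }
  cd <- S4Vectors::DataFrame(patient_id = patientId, row.names = patientId)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == n)
    for (nm in setdiff(names(covariates), "patient_id"))
      cd[[nm]] <- covariates[[nm]]
  }
  sch <- canonicalSchema()
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(endorsed = mat),
    rowData = S4Vectors::DataFrame(code = sch$code, side = sch$side,
                                   label = sch$label, row.names = sch$code),
    colData = cd
  )
  new("BodyMapCohort", se)
}

#' Binary endorsement matrix of a cohort
#'
#' @param x a \linkS4class{BodyMapCohort}
#' @return 74 x n integer matrix (codes x patients)
#' @export
endorsedMatrix <- function(x) {
  stopifnot(is(x, "BodyMapCohort"))
  SummarizedExperiment::assay(x, "endorsed")
}

#' Patient-level data of a cohort
#'
#' @param x a \linkS4class{BodyMapCohort}
#' @return data.frame of patient identifiers and covariates
#' @export
patientData <- function(x) {
  stopifnot(is(x, "BodyMapCohort"))
  as.data.frame(SummarizedExperiment::colData(x))
}

#' Serialize a cohort's endorsements back to delimited strings
#'
#' Codes are emitted sorted ascending and joined with ", ", the canonical
#' dialect; re-parsing returns the same endorsement sets.
#'
#' @param x a \linkS4class{BodyMapCohort}
#' @return character vector, one string per patient
#' @export
endorsementStrings <- function(x) {
  m <- endorsedMatrix(x)
  vapply(seq_len(ncol(m)),
         function(i) paste(rownames(m)[m[, i] == 1L], collapse = ", "),
         character(1))
}

setMethod("show", "BodyMapCohort", function(object) {
  cat(sprintf("BodyMapCohort: %d patients x 74 segments (36 front, 38 back)\n",
              ncol(object)))
  cnt <- countEndorsed(object)
  if (length(cnt))
    cat(sprintf("endorsed areas/patient: median %g, range %d-%d\n",
                stats::median(cnt), min(cnt), max(cnt)))
  covs <- setdiff(colnames(SummarizedExperiment::colData(object)),
                  "patient_id")
  if (length(covs)) cat("covariates:", paste(covs, collapse = ", "), "\n")
})

#' Read a tidy cohort CSV
#'
#' Expects the tidy export convention: a header row, one row per patient,
#' with an identifier column and a delimited endorsement-string column; any
#' further columns are kept as covariates. One-hot (74-checkbox) layouts are
#' rejected -- export the instrument as a single delimited text field
#' instead.
#'
#' @param path CSV file path
#' @param idCol name of the patient identifier column (default "id")
#' @param endorsementCol name of the endorsement string column
#'   (default "bodymap")
#' @param policy a [parsePolicy()]
#' @param quiet suppress the row-count message
#' @return a \linkS4class{BodyMapCohort}
#' @export
readCohort <- function(path, idCol = "id", endorsementCol = "bodymap",
                       policy = parsePolicy(), quiet = FALSE) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  df <- read.csv(path, colClasses = NA, stringsAsFactors = FALSE)
  for (col in c(idCol, endorsementCol)) {
    if (!col %in% names(df)) {
      onehot <- sum(grepl("^[12][0-9]{2}$|^[Xx][12][0-9]{2}$", names(df)))
      if (col == endorsementCol && onehot >= 10)
        stop("column '", col, "' not found; this looks like a one-hot ",
             "(74-checkbox) export, which is not accepted -- use a single ",
             "delimited endorsement-string field", call. = FALSE)
      stop("required column '", col, "' not found in ", path, call. = FALSE)
    }
  }
  covs <- df[, setdiff(names(df), c(idCol, endorsementCol)), drop = FALSE]
  x <- BodyMapCohort(as.character(df[[endorsementCol]]),
                     patientId = df[[idCol]],
                     covariates = if (ncol(covs)) covs else NULL,
                     policy = policy)
  if (!quiet)
    message(sprintf("read %d patient records from %s", ncol(x), path))
  x
}

#' Write a cohort as a tidy CSV
#'
#' Inverse of [readCohort()]: one row per patient, the endorsement set
#' serialized with [endorsementStrings()], covariates as further columns.
#'
#' @param x a \linkS4class{BodyMapCohort}
#' @param path output CSV path
#' @param idCol,endorsementCol column names to write
#' @return the path, invisibly
#' @export
writeCohort <- function(x, path, idCol = "id", endorsementCol = "bodymap") {
  pd <- patientData(x)
  out <- data.frame(pd$patient_id, endorsementStrings(x),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c(idCol, endorsementCol)
  for (nm in setdiff(names(pd), "patient_id")) out[[nm]] <- pd[[nm]]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
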