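#' BodyMapCohort: a cohort of body-map endorsements
#'
#' Extends \link[SummarizedExperiment]{SummarizedExperiment}. The single
#' assay \code{"endorsed"} is a 74 x n binary integer matrix (segments in
#' canonical code order x patients); \code{rowData} carries the segment
#' schema (code, side, label); \code{colData} carries patient identifiers and
#' covariates such as group labels, NRS pain intensity, or PROMIS t-scores.
#'
#' @seealso [BodyMapCohort()] (constructor), [readCohort()], [generateCohort()]
#' @exportClass BodyMapCohort
setClass("BodyMapCohort", contains = "SummarizedExperiment")

setValidity("BodyMapCohort", function(object) {
  codes <- canonicalCodes()
  if (nrow(object) != 74L)
    return(sprintf("must have exactly 74 rows, not %d", nrow(object)))
  if (!identical(rownames(object), codes))
    return("rownames must be the 74 canonical codes in ascending order")
  if (!"endorsed" %in% SummarizedExperiment::assayNames(object))
    return("assay 'endorsed' is missing")
  e <- SummarizedExperiment::assay(object, "endorsed")
  if (length(e) && !all(e %in% c(0L, 1L)))
    return("assay 'endorsed' must be binary (0/1)")
  if (!"patient_id" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData must contain a 'patient_id' column")
  pid <- SummarizedExperiment::colData(object)$patient_id
  if (anyDuplicated(pid))
    return("patient_id values must be unique")
  TRUE
})

#' CooccurrenceMatrix: pairwise segment co-occurrence counts
#'
#' A 74 x 74 symmetric nonnegative integer matrix indexed by canonical
#' segment codes, with zero diagonal. Cell (i, j) is the number of patients
#' endorsing both segment i and segment j in the same body map.
#'
#' @seealso [cooccurrenceMatrix()], [topCooccurring()]
#' @exportClass CooccurrenceMatrix
setClass("CooccurrenceMatrix", representation(counts = "matrix"))

setValidity("CooccurrenceMatrix", function(object) {
  m <- object@counts
  codes <- canonicalCodes()
  if (!identical(dim(m), c(74L, 74L)))
    return("counts must be 74 x 74")
  if (!identical(rownames(m), codes) || !identical(colnames(m), codes))
    return("dimnames must be the canonical codes")
  if (any(m < 0) || any(m != round(m)))
    return("counts must be nonnegative integers")
  if (!isSymmetric(unname(m)))
    return("counts must be symmetric")
  if (any(diag(m) != 0))
    return("diagonal must be zero")
  TRUE
})

#' ParsePolicy: how endorsement strings are tokenized
#'
#' @slot delimiter single character the string is split on (default ",");
#'   surrounding whitespace is always trimmed, so \code{"101, 102"} and
#'   \code{"101,102"} parse identically.
#' @slot duplicates \code{"dedupe"} (default; repeated codes collapse with a
#'   warning, endorsement being binary) or \code{"error"}.
#' @slot unknown \code{"error"} (default; a non-canonical token aborts,
#'   naming the token and its position) or \code{"drop"} (discard with a
#'   warning).
#'
#' @seealso [parsePolicy()]
#' @exportClass ParsePolicy
setClass("ParsePolicy", representation(
  delimiter = "character", duplicates = "character", unknown = "character"
))

setValidity("ParsePolicy", function(object) {
  if (length(object@delimiter) != 1L || nchar(object@delimiter) != 1L)
    return("delimiter must be a single character")
  if (!object@duplicates %in% c("dedupe", "error"))
    return("duplicates must be 'dedupe' or 'error'")
  if (!object@unknown %in% c("error", "drop"))
    return("unknown must be 'error' or 'drop'")
  TRUE
})

#' GeneratorConfig: parameters of the synthetic cohort generator
#'
#' Patient p draws a latent widespreadness offset w_p ~ N(0, widespreadnessSd)
#' shared across all 74 segments, and a covariate x_p (NRS: uniform integer
#' 1-10; PROMIS-like: normal mean 50 sd 10). Segment j is then endorsed
#' independently with probability
#' plogis(baselineLogit_j + groupEffect_j * [p in group B] +
#' covariateSlope_j * x_p + w_p).
#'
#' @slot n cohort size (>= 1)
#' @slot baselineLogit per-segment baseline log-odds (length 74)
#' @slot groupEffect per-segment log-odds offset for group B vs A (length 74)
#' @slot covariateModel "nrs" or "promis"
#' @slot covariateSlope per-segment log-odds per covariate unit (length 74)
#' @slot widespreadnessSd sd of the shared latent offset (>= 0)
#' @slot seed integer RNG seed
#'
#' @seealso [generatorConfig()], [generateCohort()]
#' @exportClass GeneratorConfig
setClass("GeneratorConfig", representation(
  n = "integer", baselineLogit = "numeric", groupEffect = "numeric",
  covariateModel = "character", covariateSlope = "numeric",
  widespreadnessSd = "numeric", seed = "integer"
))

setValidity("GeneratorConfig", function(object) {
  if (object@n < 1L) return("n must be >= 1")
  for (s in c("baselineLogit", "groupEffect", "covariateSlope"))
    if (length(slot(object, s)) != 74L)
      return(sprintf("%s must have length 74", s))
  if (!object@covariateModel %in% c("nrs", "promis"))
    return("covariateModel must be 'nrs' or 'promis'")
  if (object@widespreadnessSd < 0) return("widespreadnessSd must be >= 0")
  TRUE
})

#' RenderSpec: appearance of rendered documents
#'
#' @slot palette ordered colour ramp (2+ colours, low to high)
#' @slot domain numeric(0) for automatic value domain, or c(lo, hi)
#' @slot labels draw three-digit code labels at segment anchors
#' @slot title document title text ("" for none)
#'
#' @seealso [renderSpec()], [renderBodyMap()]
#' @exportClass RenderSpec
setClass("RenderSpec", representation(
  palette = "character", domain = "numeric", labels = "logical",
  title = "character"
))

setValidity("RenderSpec", function(object) {
  if (length(object@palette) < 2L)
    return("palette needs at least two colours")
  if (!length(object@domain) %in% c(0L, 2L))
    return("domain must be numeric(0) or c(lo, hi)")
  if (length(object@domain) == 2L && object@domain[1] >= object@domain[2])
    return("explicit domain must have lo < hi")
  TRUE
})
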