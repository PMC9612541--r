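#' Default baseline endorsement prevalences
#'
#' Illustrative per-segment baseline probabilities (at covariate effect zero
#' and latent offset zero) used by the synthetic generator. They follow the
#' clinical gradient of chronic-pain body maps -- lower back and posterior
#' neck most prevalent, distal extremities least -- and sum to about six
#' areas per patient, giving a median endorsed-area count near five. They
#' are illustrative defaults, not estimates from any patient dataset.
#'
#' @return numeric vector of 74 probabilities named by code
#' @examples
#' range(defaultBaselinePrevalence())
#' @export
defaultBaselinePrevalence <- function() {
  p <- c(
    # front
    "101" = .07, "102" = .07, "103" = .05, "104" = .05,
    "105" = .10, "106" = .10, "107" = .13, "108" = .05, "109" = .05,
    "110" = .13, "111" = .06, "112" = .06, "113" = .05, "114" = .05,
    "115" = .05, "116" = .06, "117" = .06, "118" = .05, "119" = .05,
    "120" = .09, "121" = .04, "122" = .04, "123" = .09, "124" = .05,
    "125" = .06, "126" = .08, "127" = .08, "128" = .06, "129" = .10,
    "130" = .10, "131" = .06, "132" = .06, "133" = .06, "134" = .06,
    "135" = .07, "136" = .07,
    # back
    "201" = .07, "202" = .07, "203" = .06, "204" = .06,
    "205" = .16, "206" = .16, "207" = .13, "208" = .13, "209" = .13,
    "210" = .13, "211" = .06, "212" = .10, "213" = .10, "214" = .06,
    "215" = .05, "216" = .05, "217" = .05, "218" = .22, "219" = .22,
    "220" = .05, "221" = .05, "222" = .09, "223" = .08, "224" = .08,
    "225" = .09, "226" = .05, "227" = .06, "228" = .08, "229" = .08,
    "230" = .06, "231" = .10, "232" = .10, "233" = .06, "234" = .06,
    "235" = .06, "236" = .06, "237" = .07, "238" = .07
  )
  stopifnot(identical(names(p), canonicalCodes()))
  p
}

#' Configure the synthetic cohort generator
#'
#' Scalar effect arguments are recycled across the 74 segments. Per-segment
#' vectors may be supplied in canonical code order, or named by code, in
#' which case unnamed segments keep their default (0 for effects, the
#' default baseline for \code{baselineLogit}): e.g.
#' \code{groupEffect = c("218" = 0.8)} shifts only the lower back.
#'
#' @param n cohort size
#' @param baselineLogit per-segment baseline log-odds; default
#'   \code{qlogis(defaultBaselinePrevalence())}
#' @param groupEffect per-segment log-odds offset for group B vs A
#'   (default 0)
#' @param covariateModel "nrs" (uniform integers 1-10) or "promis"
#'   (normal, mean 50, sd 10)
#' @param covariateSlope per-segment log-odds per covariate unit (default 0)
#' @param widespreadnessSd sd of the per-patient latent offset shared across
#'   segments (default 1); positive values induce cross-segment dependence
#'   and the right-skewed area-count distribution seen in real cohorts
#' @param seed integer RNG seed
#' @return a \linkS4class{GeneratorConfig}
#' @examples
#' cfg <- generatorConfig(n = 50, seed = 1)
#' @export
generatorConfig <- function(n,
                            baselineLogit = qlogis(defaultBaselinePrevalence()),
                            groupEffect = 0,
                            covariateModel = c("nrs", "promis"),
                            covariateSlope = 0,
                            widespreadnessSd = 1,
                            seed = 1) {
  # scalars recycle across segments; named vectors override the fill
  # per code; unnamed length-74 vectors are taken in canonical order
  expand <- function(v, what, fill = 0) {
    if (is.null(names(v))) {
      if (length(v) == 1L) v <- rep(v, 74)
      if (length(v) != 74L)
        stop(what, " must be a scalar, a length-74 vector, or named by code",
             call. = FALSE)
    } else {
      sideOf(names(v))
      full <- rep_len(fill, 74)
      names(full) <- canonicalCodes()
      full[names(v)] <- v
      v <- full
    }
    if (anyNA(v)) stop(what, " contains NA", call. = FALSE)
    unname(v)
  }
  new("GeneratorConfig",
      n = as.integer(n),
      baselineLogit = expand(baselineLogit, "baselineLogit",
                             fill = qlogis(defaultBaselinePrevalence())),
      groupEffect = expand(groupEffect, "groupEffect"),
      covariateModel = match.arg(covariateModel),
      covariateSlope = expand(covariateSlope, "covariateSlope"),
      widespreadnessSd = widespreadnessSd,
      seed = as.integer(seed))
}

#' Generate a seeded synthetic cohort
#'
#' For patient p, draws a latent widespreadness offset
#' w_p ~ N(0, widespreadnessSd) and a covariate x_p, assigns the first
#' half of the cohort to group "A" and the rest to "B", and endorses
#' segment j independently (given w_p) with probability
#' \deqn{\mathrm{logit}^{-1}(\beta_{0j} + \gamma_j [p \in B] +
#'   \beta_{1j} x_p + w_p).}
#' Endorsements are serialized as comma-delimited strings internally, so
#' the result is identical to reading the equivalent tidy CSV. The global
#' RNG state is restored on exit; output is fully determined by the config
#' (including its seed).
#'
#' @param config a [generatorConfig()]
#' @return a \linkS4class{BodyMapCohort} with covariates \code{group}
#'   ("A"/"B") and \code{nrs} or \code{promis}
#' @examples
#' bmc <- generateCohort(generatorConfig(n = 30, seed = 9))
#' table(patientData(bmc)$group)
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  }
  set.seed(config@seed)
  n <- config@n
  group <- rep(c("A", "B"), c(ceiling(n / 2), floor(n / 2)))
  x <- switch(config@covariateModel,
              nrs = sample(1:10, n, replace = TRUE),
              promis = rnorm(n, mean = 50, sd = 10))
  w <- rnorm(n, 0, config@widespreadnessSd)
  # 74 x n matrix of endorsement log-odds
  eta <- outer(config@baselineLogit, rep(1, n)) +
    outer(config@groupEffect, as.numeric(group == "B")) +
    outer(config@covariateSlope, as.numeric(x)) +
    matrix(w, nrow = 74, ncol = n, byrow = TRUE)
  endorsed <- matrix(rbinom(74L * n, 1L, plogis(eta)), nrow = 74)
  codes <- canonicalCodes()
  strings <- vapply(seq_len(n),
                    function(i) paste(codes[endorsed[, i] == 1L],
                                      collapse = ", "),
                    character(1))
  covs <- data.frame(group = group, stringsAsFactors = FALSE)
  covs[[config@covariateModel]] <- x
  BodyMapCohort(strings, patientId = sprintf("S%05d", seq_len(n)),
                covariates = covs)
}

#' The two-patient worked-example cohort
#'
#' Two patients: one endorsing "101, 102, 103, 104, 201, 202" and the other
#' "101, 102, 201, 202". On this cohort segment 101 co-occurs with 103 and
#' 104 once but with 102, 201 and 202 twice -- the reference example for
#' [cooccurrenceMatrix()].
#'
#' @return a \linkS4class{BodyMapCohort} of two patients
#' @examples
#' countEndorsed(workedExampleCohort())
#' @export
workedExampleCohort <- function() {
  BodyMapCohort(c("101, 102, 103, 104, 201, 202", "101, 102, 201, 202"),
                patientId = c("patient1", "patient2"))
}
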