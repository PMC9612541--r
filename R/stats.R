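#' Two-proportion z-test
#'
#' Classical pooled-variance test of H0: p1 = p2 for endorsement proportions
#' k1/n1 vs k2/n2,
#' \deqn{z = \frac{\hat p_1 - \hat p_2}
#'   {\sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}},
#'   \quad \hat p = \frac{k_1 + k_2}{n_1 + n_2},}
#' with p-values from the standard normal: left tail Phi(z), right tail
#' 1 - Phi(z), two-sided 2 min(left, right). No continuity correction is
#' applied by default, which keeps the one-/two-sided doubling identity
#' exact; set \code{pooled = FALSE} for the unpooled (Wald) variance
#' estimate.
#'
#' When the pooled proportion is 0 or 1 the variance vanishes and the test
#' is undefined; the result is flagged \code{"degenerate"} with NA statistic
#' and p-value.
#'
#' @param k1,n1 endorsements and size of group 1
#' @param k2,n2 endorsements and size of group 2
#' @param tail "two" (default), "left" or "right"
#' @param pooled use the pooled variance estimate (default TRUE)
#' @return list with elements \code{z}, \code{p}, \code{flag}
#' @examples
#' twoProportionZTest(10, 100, 20, 100)
#' @export
twoProportionZTest <- function(k1, n1, k2, n2,
                               tail = c("two", "left", "right"),
                               pooled = TRUE) {
  tail <- match.arg(tail)
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  phat <- (k1 + k2) / (n1 + n2)
  if (phat %in% c(0, 1))
    return(list(z = NA_real_, p = NA_real_, flag = "degenerate"))
  p1 <- k1 / n1
  p2 <- k2 / n2
  se <- if (pooled) {
    sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  } else {
    sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  }
  if (se == 0)
    return(list(z = NA_real_, p = NA_real_, flag = "degenerate"))
  z <- (p1 - p2) / se
  left <- pnorm(z)
  p <- switch(tail, left = left, right = 1 - left,
              two = 2 * min(left, 1 - left))
  list(z = z, p = min(p, 1), flag = "ok")
}

#' Multiplicity-adjust p-values
#'
#' Bonferroni by default: \code{p_adj = min(1, p * m)} with the family size
#' \code{m} fixed at the full number of tests (74 when testing every
#' segment) -- the clamp at 1 is what produces runs of adjusted p-values
#' printed as exactly 1. \code{method} may also be "none", any method name
#' accepted by [stats::p.adjust()], or a user function \code{f(p, m)}.
#'
#' @param p numeric vector of raw p-values in [0, 1] (NAs pass through)
#' @param method "bonferroni" (default), "none", a [stats::p.adjust()]
#'   method name, or a function of (p, m)
#' @param m family size; defaults to \code{length(p)}
#' @return adjusted p-values, same length and order as \code{p}
#' @examples
#' adjustPValues(c(1e-4, 0.05), m = 74)
#' @export
adjustPValues <- function(p, method = "bonferroni", m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stopifnot(m >= length(p))
  if (is.function(method)) return(method(p, m))
  method <- match.arg(method, c("bonferroni", "none", stats::p.adjust.methods))
  switch(method,
         bonferroni = pmin(1, p * m),
         none = p,
         stats::p.adjust(p, method = method, n = m))
}

.resolveGroups <- function(a, b, groupCol) {
  if (is.null(b)) {
    if (is.null(groupCol))
      stop("supply either a second cohort or groupCol", call. = FALSE)
    g <- patientData(a)[[groupCol]]
    if (is.null(g))
      stop("no column '", groupCol, "' in cohort covariates", call. = FALSE)
    lev <- sort(unique(as.character(g)))
    if (length(lev) != 2L)
      stop("groupCol must have exactly two levels, found ",
           length(lev), call. = FALSE)
    list(a = a[, g == lev[1]], b = a[, g == lev[2]], levels = lev)
  } else {
    list(a = a, b = b, levels = c("A", "B"))
  }
}

#' Per-segment two-proportion z-tests between two groups
#'
#' For each of the 74 segments, tallies endorsement in each group and runs
#' [twoProportionZTest()]; raw p-values are then multiplicity-adjusted over
#' the full family of 74 segments (Bonferroni by default, so
#' \code{p_adj = min(1, 74 p_raw)}). Segments endorsed by no one (or
#' everyone) across both groups carry a degenerate flag and NA results, but
#' still count toward the family size.
#'
#' @param a a \linkS4class{BodyMapCohort} (group A, or the whole cohort if
#'   \code{groupCol} is used)
#' @param b optional second cohort (group B)
#' @param groupCol alternatively, a two-level covariate column of \code{a}
#'   to split on (levels sorted; first = group A)
#' @param tail tail of the test: proportion in A less than ("left"),
#'   greater than ("right"), or different from ("two", default) B
#' @param correction multiplicity correction, see [adjustPValues()]
#' @return data.frame with 74 rows: id, label, side, prop_a, prop_b,
#'   statistic (z), p_raw, p_adj, flag -- ordered by code
#' @examples
#' set.seed(1)
#' bmc <- generateCohort(generatorConfig(n = 120, seed = 7))
#' res <- compareGroupsZTest(bmc, groupCol = "group")
#' head(res[order(res$p_raw), ])
#' @export
compareGroupsZTest <- function(a, b = NULL, groupCol = NULL,
                               tail = c("two", "left", "right"),
                               correction = "bonferroni") {
  tail <- match.arg(tail)
  gr <- .resolveGroups(a, b, groupCol)
  if (ncol(gr$a) == 0L || ncol(gr$b) == 0L)
    stop("both groups must contain at least one patient", call. = FALSE)
  ka <- rowSums(endorsedMatrix(gr$a))
  kb <- rowSums(endorsedMatrix(gr$b))
  na <- ncol(gr$a)
  nb <- ncol(gr$b)
  sch <- canonicalSchema()
  z <- p <- rep(NA_real_, 74)
  flag <- character(74)
  for (i in 1:74) {
    r <- twoProportionZTest(ka[i], na, kb[i], nb, tail = tail)
    z[i] <- r$z
    p[i] <- r$p
    flag[i] <- r$flag
  }
  data.frame(
    id = sch$code, label = sch$label, side = sch$side,
    prop_a = unname(ka) / na, prop_b = unname(kb) / nb,
    statistic = z, p_raw = p,
    p_adj = adjustPValues(p, correction, m = 74),
    flag = flag, stringsAsFactors = FALSE
  )
}

#' Per-segment logistic regression on a continuous covariate
#'
#' For each segment j fits, by maximum likelihood (IRLS, tolerance 1e-8,
#' at most 25 iterations),
#' \deqn{\mathrm{logit}\, P(\mathrm{endorse}_j) = \beta_0 + \beta_1 x,}
#' reporting the slope estimate and its Wald p-value, multiplicity-adjusted
#' over the 74-segment family. Segments that are never (or always) endorsed,
#' and fits showing complete separation or non-convergence, are flagged
#' degenerate with NA results rather than a fabricated estimate.
#'
#' @param x a \linkS4class{BodyMapCohort}
#' @param covariate name of a numeric covariate column (e.g. NRS pain
#'   intensity 1-10, or a PROMIS t-score) with at least two distinct values
#' @param correction multiplicity correction, see [adjustPValues()]
#' @return data.frame with 74 rows: id, label, side, statistic (the slope
#'   beta1), p_raw, p_adj, flag
#' @examples
#' bmc <- generateCohort(generatorConfig(n = 150, covariateSlope = 0.2,
#'                                       widespreadnessSd = 0, seed = 3))
#' res <- endorsementGLM(bmc, "nrs")
#' median(res$statistic, na.rm = TRUE)
#' @export
endorsementGLM <- function(x, covariate, correction = "bonferroni") {
  cov <- patientData(x)[[covariate]]
  if (is.null(cov))
    stop("no column '", covariate, "' in cohort covariates", call. = FALSE)
  if (!is.numeric(cov))
    stop("covariate '", covariate, "' must be numeric", call. = FALSE)
  if (length(unique(cov)) < 2L)
    stop("covariate '", covariate, "' needs at least two distinct values",
         call. = FALSE)
  if (ncol(x) < 1L) stop("cohort is empty", call. = FALSE)
  m <- endorsedMatrix(x)
  sch <- canonicalSchema()
  beta <- p <- rep(NA_real_, 74)
  flag <- rep("degenerate", 74)
  for (i in 1:74) {
    y <- m[i, ]
    if (all(y == 0L) || all(y == 1L)) next
    separated <- FALSE
    fit <- withCallingHandlers(
      glm(y ~ cov, family = binomial(),
          control = glm.control(epsilon = 1e-8, maxit = 25)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
            grepl("did not converge", conditionMessage(w)))
          separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    if (separated || !fit$converged) next
    co <- summary(fit)$coefficients
    beta[i] <- co["cov", "Estimate"]
    p[i] <- co["cov", "Pr(>|z|)"]
    flag[i] <- "ok"
  }
  data.frame(
    id = sch$code, label = sch$label, side = sch$side,
    statistic = beta, p_raw = p,
    p_adj = adjustPValues(p, correction, m = 74),
    flag = flag, stringsAsFactors = FALSE
  )
}

#' Subtract one body map from another
#'
#' Per-segment difference \code{a - b}, e.g. percent endorsement in women
#' minus percent endorsement in men; values may be negative, and the result
#' is rendered with a diverging palette centred at zero.
#'
#' @param a,b body-map tables on the same 74-code schema
#' @return a body-map table of differences
#' @examples
#' d <- differenceMap(bodyMapTable(c("218" = 30)), bodyMapTable(c("218" = 20)))
#' d$value[d$id == "218"]
#' @export
differenceMap <- function(a, b) {
  .assertBodyMapTable(a)
  .assertBodyMapTable(b)
  a <- a[order(a$id), ]
  b <- b[order(b$id), ]
  a$value <- a$value - b$value
  rownames(a) <- NULL
  a
}

#' Stratify p-values into presentation significance levels
#'
#' The strata used in the plots' legends: \code{***} p < 0.001, \code{**}
#' p < 0.01, \code{*} p < 0.05, \code{ns} otherwise (NA for degenerate
#' results).
#'
#' @param p numeric vector of (adjusted) p-values
#' @return ordered factor with levels ns < * < ** < ***
#' @examples
#' significanceStrata(c(0.2, 0.04, 0.0005, NA))
#' @export
significanceStrata <- function(p) {
  lab <- ifelse(is.na(p), NA,
                ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**",
                              ifelse(p < 0.05, "*", "ns"))))
  factor(lab, levels = c("ns", "*", "**", "***"), ordered = TRUE)
}

#' Write a per-segment test-result table to CSV
#'
#' @param results a result data.frame from [compareGroupsZTest()] or
#'   [endorsementGLM()]
#' @param path output file path
#' @return the path, invisibly
#' @export
writeTestResults <- function(results, path) {
  stopifnot(all(c("id", "label", "statistic", "p_raw", "p_adj", "flag")
                %in% names(results)))
  write.csv(results, path, row.names = FALSE)
  invisible(path)
}
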