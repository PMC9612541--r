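test_that("pooled two-proportion z-test matches the classical formula", {
  # equal proportions: z = 0, two-sided p = 1
  r <- twoProportionZTest(5, 50, 10, 100)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)

  # frozen reference value, checked against the pooled-variance formula
  r <- twoProportionZTest(10, 100, 20, 100)
  expect_equal(r$z, -1.980295, tolerance = 1e-6)
  expect_equal(r$p, 0.0476704, tolerance = 1e-5)

  # zero pooled variance is flagged degenerate, no statistic fabricated
  r0 <- twoProportionZTest(0, 50, 0, 50)
  expect_identical(r0$flag, "degenerate")
  expect_true(is.na(r0$z) && is.na(r0$p))
  r1 <- twoProportionZTest(50, 50, 50, 50)
  expect_identical(r1$flag, "degenerate")
})

test_that("z-test agrees with prop.test as an independent cross-check", {
  set.seed(5)
  for (i in 1:25) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    k1 <- rbinom(1, n1, 0.3); k2 <- rbinom(1, n2, 0.4)
    phat <- (k1 + k2) / (n1 + n2)
    if (phat %in% c(0, 1)) next
    r <- twoProportionZTest(k1, n1, k2, n2)
    pt <- suppressWarnings(prop.test(c(k1, k2), c(n1, n2), correct = FALSE))
    expect_equal(r$z^2, unname(pt$statistic), tolerance = 1e-10)
    expect_equal(r$p, pt$p.value, tolerance = 1e-10)
  }
})

test_that("tail handling: doubling identity and antisymmetry under swap", {
  set.seed(6)
  for (i in 1:20) {
    k1 <- rbinom(1, 80, 0.3); k2 <- rbinom(1, 120, 0.4)
    left <- twoProportionZTest(k1, 80, k2, 120, tail = "left")
    right <- twoProportionZTest(k1, 80, k2, 120, tail = "right")
    two <- twoProportionZTest(k1, 80, k2, 120, tail = "two")
    expect_equal(two$p, 2 * min(left$p, right$p), tolerance = 1e-12)
    swapped <- twoProportionZTest(k2, 120, k1, 80)
    expect_equal(swapped$z, -two$z, tolerance = 1e-12)
  }
})

test_that("Bonferroni adjustment multiplies by the family size and clamps", {
  expect_equal(adjustPValues(1e-4, m = 74), 0.0074)
  expect_equal(adjustPValues(0.05, m = 74), 1)
  p <- sort(runif(74))
  expect_identical(adjustPValues(p), pmin(1, p * 74))
  expect_false(is.unsorted(adjustPValues(p)))      # order-preserving
  expect_true(all(adjustPValues(p) >= p))
  expect_error(adjustPValues(c(0.5, 1.2)), "\\[0, 1\\]")
  # named p.adjust methods and user-supplied functions are honoured
  expect_equal(adjustPValues(p, "holm"), p.adjust(p, "holm"))
  expect_equal(adjustPValues(p, "none"), p)
  expect_equal(adjustPValues(p, function(p, m) pmin(1, p * m / 2)),
               pmin(1, p * 37))
})

test_that("group comparison tests every segment with a 74-wide family", {
  bmc <- generateCohort(generatorConfig(n = 200, seed = 31))
  res <- compareGroupsZTest(bmc, groupCol = "group")
  expect_identical(nrow(res), 74L)
  expect_identical(res$id, canonicalCodes())
  expect_identical(res$label, canonicalSchema()$label)
  ok <- res$flag == "ok"
  expect_equal(res$p_adj[ok], pmin(1, res$p_raw[ok] * 74))
  expect_true(all(res$p_adj[ok] >= res$p_raw[ok]))

  # identical groups: z = 0, adjusted p = 1 everywhere non-degenerate
  same <- compareGroupsZTest(bmc, bmc)
  ok <- same$flag == "ok"
  expect_true(any(ok))
  expect_true(all(same$statistic[ok] == 0))
  expect_true(all(same$p_adj[ok] == 1))

  # a segment endorsed by no one in either group is degenerate
  tiny <- BodyMapCohort(c("101", "102"), patientId = c("u", "v"),
                        covariates = data.frame(group = c("A", "B")))
  res2 <- compareGroupsZTest(tiny, groupCol = "group")
  expect_identical(res2$flag[res2$id == "218"], "degenerate")
  expect_true(is.na(res2$p_adj[res2$id == "218"]))

  expect_error(compareGroupsZTest(bmc[, 0], bmc), "at least one patient")
  expect_error(compareGroupsZTest(bmc, groupCol = "absent"), "absent")
})

test_that("an induced prevalence shift is detected at its segment", {
  # group A prevalence 0.10 vs group B 0.30 at segment 218 only
  base <- qlogis(defaultBaselinePrevalence())
  base["218"] <- qlogis(0.10)
  shift <- setNames(rep(0, 74), canonicalCodes())
  shift["218"] <- qlogis(0.30) - qlogis(0.10)
  hits <- unique_hits <- 0L
  nrep <- 60L
  for (r in seq_len(nrep)) {
    bmc <- generateCohort(generatorConfig(
      n = 1000, baselineLogit = base, groupEffect = shift,
      widespreadnessSd = 0, seed = 7000 + r))
    res <- compareGroupsZTest(bmc, groupCol = "group", tail = "left")
    sig <- res$id[!is.na(res$p_adj) & res$p_adj < 0.05]
    if ("218" %in% sig) hits <- hits + 1L
    if (identical(sig, "218")) unique_hits <- unique_hits + 1L
  }
  expect_identical(hits, nrep)           # the shifted segment is always found
  expect_gte(unique_hits / nrep, 0.9)    # and almost always uniquely
})

test_that("per-segment logistic regression recovers slopes and flags
           degenerate fits", {
  bmc <- generateCohort(generatorConfig(n = 800, covariateSlope = 0.2,
                                        widespreadnessSd = 0, seed = 13))
  res <- endorsementGLM(bmc, "nrs")
  expect_identical(nrow(res), 74L)
  ok <- res$flag == "ok"
  expect_gt(mean(ok), 0.9)
  expect_equal(mean(res$statistic[ok]), 0.2, tolerance = 0.25)
  expect_equal(res$p_adj[ok], pmin(1, res$p_raw[ok] * 74))

  # cross-check one fit against glm directly
  y <- endorsedMatrix(bmc)["218", ]
  x <- patientData(bmc)$nrs
  fit <- glm(y ~ x, family = binomial())
  expect_equal(res$statistic[res$id == "218"], unname(coef(fit)[2]),
               tolerance = 1e-6)

  # a never-endorsed segment carries a degenerate flag and no estimate
  fixed <- BodyMapCohort(rep(c("101", "101, 102"), 10),
                         patientId = paste0("p", 1:20),
                         covariates = data.frame(score = rnorm(20)))
  res2 <- endorsementGLM(fixed, "score")
  expect_identical(res2$flag[res2$id == "218"], "degenerate")
  expect_true(is.na(res2$statistic[res2$id == "218"]))
  # an always-endorsed segment likewise
  expect_identical(res2$flag[res2$id == "101"], "degenerate")
})

test_that("complete separation is flagged, not reported as an estimate", {
  x <- 1:20
  strings <- ifelse(x > 10, "218", "")
  bmc <- BodyMapCohort(strings, patientId = paste0("p", 1:20),
                       covariates = data.frame(score = as.numeric(x)))
  res <- endorsementGLM(bmc, "score")
  expect_identical(res$flag[res$id == "218"], "degenerate")
  expect_true(is.na(res$statistic[res$id == "218"]))
})

test_that("glm covariate validation", {
  bmc <- workedExampleCohort()
  expect_error(endorsementGLM(bmc, "nrs"), "nrs")
  bmc2 <- BodyMapCohort(c("101", "102"), patientId = c("a", "b"),
                        covariates = data.frame(s = c(1, 1)))
  expect_error(endorsementGLM(bmc2, "s"), "distinct")
})

test_that("under a null covariate few segments reach adjusted significance", {
  frac <- vapply(1:25, function(r) {
    bmc <- generateCohort(generatorConfig(n = 200, widespreadnessSd = 0,
                                          seed = 9000 + r))
    res <- endorsementGLM(bmc, "nrs")
    mean(res$p_adj < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("difference maps subtract per segment and are antisymmetric", {
  f <- bodyMapTable(c("218" = 30))
  m <- bodyMapTable(c("218" = 20, "101" = 5))
  d <- differenceMap(f, m)
  expect_identical(d$value[d$id == "218"], 10)
  expect_identical(d$value[d$id == "101"], -5)
  expect_identical(differenceMap(f, f)$value, rep(0, 74))
  expect_identical(differenceMap(m, f)$value, -d$value)
})

test_that("significance strata follow the plotting legend convention", {
  out <- significanceStrata(c(0.2, 0.04, 0.009, 0.0005, NA))
  expect_identical(as.character(out), c("ns", "*", "**", "***", NA))
  expect_true(is.ordered(out))
})
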