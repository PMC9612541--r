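---
title: "Statistical methods for body-map endorsement data"
author: "bodymapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for body-map endorsement data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodymapr)
```

## The data and its code system

A body-map assessment asks a patient to mark every region of a segmented
human silhouette where they experience pain. The instrument bodymapr
targets divides the body into 74 regions — 36 on the anterior surface and
38 on the posterior — each carrying a three-digit code whose leading digit
encodes the side (1 = front, 2 = back). An export from an electronic
capture system is tidy: one row per patient, with the endorsed codes
concatenated into one delimited string such as `"101, 102, 201, 202"`.
Endorsement is binary per segment per patient; there is no intensity
information in the string itself.

The male and female silhouettes of the original instrument carry distinct
code systems. The published segment registry, however, uses a single
unified space, and the cross-silhouette correspondence table is not
public. bodymapr therefore computes everything in the unified 74-code
space and exposes `convertMap()` / `convertMaps()`, which apply any
user-supplied side-preserving bijection stored as a two-column CSV; the
packaged default is the identity. If a correspondence table becomes
available it can be dropped in by path without code changes.

Codes are stored as character strings throughout. They are identifiers,
not quantities; keeping them as text preserves the leading-digit
semantics and makes arithmetic on them impossible by construction.

## Parsing policy

Exports in the wild differ in small ways, so tokenization is governed by
an explicit `parsePolicy()`:

* **Delimiter** (default `","`): the string is split on the delimiter and
  each token is trimmed, so `"101, 102"` and `"101,102"` parse
  identically.
* **Duplicates** (default dedupe-with-warning): endorsement is binary, so
  a repeated code carries no information; a strict mode errors instead.
* **Unknown tokens** (default error, carrying the token and its
  position): silently guessing at typos in clinical data is worse than
  failing loudly; a drop-with-warning mode exists for exploratory use.
* **Empty strings** parse to the empty set. Patients with no pain
  locations are real observations and must survive into area-count
  histograms and denominators.

One-hot (74-checkbox) exports are rejected with a pointed error: the
supported contract is the delimited-string field, and accepting both
silently would make column-name typos indistinguishable from layout
changes.

## The cohort container

`BodyMapCohort` extends `SummarizedExperiment`: the assay is the
74 × n binary endorsement matrix in canonical code order, row data carry
the segment registry (code, side, anatomical label), and column data
carry patient identifiers and covariates. This gives subsetting,
alignment and metadata handling for free and keeps every analysis a pure
function of one object. The per-segment "body-map table" — a 74-row
data.frame with columns `id`, `group` (front/back) and `value` — remains
the exchange currency for aggregation, differences and plotting, written
and read as plain CSV sorted by code so files diff deterministically.

## Between-group comparison

`compareGroupsZTest()` tallies per-segment endorsement counts in each
group and applies the classical pooled two-proportion z-test

$$z_j = \frac{\hat p_{1j} - \hat p_{2j}}
{\sqrt{\hat p_j (1-\hat p_j)\left(\tfrac1{n_1}+\tfrac1{n_2}\right)}},
\qquad \hat p_j = \frac{k_{1j}+k_{2j}}{n_1+n_2},$$

with left-, right- or two-tailed p-values from the standard normal. No
continuity correction is applied by default: the uncorrected score
statistic keeps the identity p_two = 2·min(p_left, p_right) exact and
matches the uncorrected chi-square test (z² = X²), which the test suite
verifies against `prop.test(correct = FALSE)`. The unpooled (Wald)
variance is available via `pooled = FALSE` for users who prefer it; at
the sample sizes where these instruments are analyzed the two differ
negligibly.

**Multiplicity.** The family size is fixed at 74 — one test per
anatomical location — even when some segments are degenerate, because the
inferential family is the instrument, not the subset of segments that
happened to vary. Bonferroni is the default, p_adj = min(1, 74·p_raw);
the clamp is why result tables for weak effects show runs of adjusted
p-values equal to exactly 1. Any `p.adjust` method name or a user
function `f(p, m)` may be substituted.

**Degeneracy.** A segment endorsed by no one (or everyone) across both
groups has zero pooled variance; the test is undefined. Such segments are
flagged `degenerate` and carry `NA` statistics — reporting a fabricated
z of 0 or ±∞ would be worse than honesty.

## Covariate models

`endorsementGLM()` fits, per segment, the logistic regression
logit P(endorseⱼ) = β₀ + β₁x by maximum likelihood (IRLS with tolerance
10⁻⁸ and at most 25 iterations, via `stats::glm`), reporting the slope
and its Wald p-value under the same 74-wide correction. All-zero or
all-one segments are flagged up front; complete separation and
non-convergence are detected from the fitter's diagnostics and flagged
rather than reported as estimates, since a separated logistic fit has no
finite MLE.

A caveat worth stating: when endorsement is generated with a shared
latent per-patient factor (see below), the marginal slope estimated by a
GLM that omits that factor is attenuated relative to the
conditional slope — logistic models are not collapsible. Parameter
recovery is therefore checked under the GLM's own sampling model
(latent factor off), and estimates from real, heterogeneous cohorts
should be read as marginal (population-averaged) effects.

## Co-occurrence

Co-occurrence of two segments is the number of patients endorsing both in
the same body map; each patient contributes at most once per pair. With
E the binary endorsement matrix the count matrix is E E′ with its
diagonal zeroed — symmetric, nonnegative, and spanning 74 × 73 = 5,402
off-diagonal cells (each unordered pair counted in both orientations; the
5,402 figure refers to this ordered cell space, 2,701 unordered pairs).
The test suite checks the matrix-product implementation against a
brute-force enumeration of all within-patient pairs. `topCooccurring()`
ranks unordered pairs by count, breaking ties by first then second code
ascending — a reporting convention, since no canonical order exists among
tied pairs — and drops never-co-endorsed pairs.

## The synthetic generator

`generateCohort()` exists so that every statistic and plot in the package
is exercised end-to-end without patient data. For patient p it draws a
latent widespreadness offset w_p ~ N(0, σ_w), a covariate (NRS: uniform
integers 1–10; PROMIS-like: normal mean 50, SD 10), assigns groups A/B
half-and-half, and endorses segment j independently given w_p with
probability logistic(β₀ⱼ + γⱼ·[B] + β₁ⱼ·x_p + w_p).

Defaults, chosen once and documented rather than tuned:

* **Baseline prevalences** (0.04–0.22 per segment) follow the clinical
  gradient of chronic-pain maps — lower back and posterior neck highest,
  distal extremities lowest — and sum to ≈ 6 expected areas per patient,
  giving a median endorsed-area count near 5, consistent with cohorts in
  which most patients endorse between one and ten locations. They are
  illustrative, not estimates of any real cohort.
* **σ_w = 1** by default. Conditional independence across segments given
  one shared latent factor is the simplest mechanism that produces both
  positive cross-segment co-occurrence and the right-skewed area-count
  distribution real cohorts show; the skew is verified by test. It does
  not emulate anatomically local dependence (e.g. neighbouring segments
  co-endorsed beyond what widespreadness explains), so passing tests say
  nothing about spatially structured pain patterns.
* **Calibration configurations** set σ_w = 0. The latent factor leaves
  each segment's marginal null distribution Bernoulli-i.i.d. across
  patients (so the per-segment test's size is unaffected) but correlates
  segments within a replicate, inflating the Monte Carlo error of
  rate estimates; and slope recovery is a property of the GLM under its
  own model, per the non-collapsibility note above. "Null" means group
  and covariate effects zero.

Generation is deterministic given the config seed, restores the caller's
RNG state, and round-trips exactly through the CSV reader/writer.

## Rendering

Two rendering paths serve different needs. The ggplot2 functions return
customisable grammar-of-graphics objects for interactive work. The
`render*()` functions emit standalone SVG documents with a fixed element
order and fixed 2-decimal coordinates, so identical inputs produce
byte-identical files — the property that makes graphical output testable
and diffable. A body-map document contains exactly one `<polygon>` per
segment (36 classed `front`, 38 classed `back`), a colour bar, and
optional code labels.

The packaged geometry is a deliberately schematic, synthetic rectangle
layout honouring the instrument's segmentation logic — symmetric
left/right segments, head/trunk/limb order, 36/38 panel split,
non-overlapping interiors — because the original silhouette artwork is
not redistributable. Anterior panels are drawn as the patient faces the
viewer (patient's right on the viewer's left, anchored by the registry's
left/right labels); posterior panels are drawn from behind. Any geometry
CSV with the same columns can be substituted by path.

Colour conventions: sequential light-to-dark for counts and percentages;
diverging, centred at zero, with a symmetric automatic domain
[−max|v|, +max|v|] for difference maps; dark-to-light for co-occurrence
heatmaps so lighter cells mark more frequently co-endorsed pairs.
Degenerate/NA values render grey. Colour position is monotone in value by
construction of the ramp interpolation.

## Significance presentation

For body-map displays of test results, p-values are stratified as
\* p < 0.05, \*\* p < 0.01, \*\*\* p < 0.001, and ns otherwise
(`significanceStrata()`), the legend convention used by the package's
figures.

## Problem sizes and numerical choices

The simulation-backed checks use sizes chosen to make Monte Carlo error
small relative to the tolerances they assert: null z-test calibration
uses 200 replicates of 500 patients per group (14,800 segment-tests;
binomial SE of the rejection-rate estimate ≈ 0.002); family-wise error
uses the same 200 replicates; logistic slope recovery uses one cohort of
2,000 (mean slope over ~74 segments, SE ≈ 0.004); generator prevalence
recovery uses 10,000 patients against a 3·√(p(1−p)/n) ≈ 0.013 binomial
bound; oracle equivalence uses 100 random cohorts of up to 50 patients.
Degenerate inputs are handled by flagging, never by silent omission:
family sizes stay at 74, and flagged segments propagate `NA` into
adjusted p-values.

## Known limitations

* The schematic geometry is topologically faithful but not
  anatomically proportioned; publication figures should substitute
  licensed artwork via the geometry asset.
* The generator's single-factor dependence cannot mimic
  condition-specific regional clustering; co-occurrence analyses of
  synthetic data reflect widespreadness only.
* The z-test relies on the normal approximation; at very low prevalence
  and small n, exact tests would be preferable (not currently provided).
* Only two-group comparisons and single-covariate models are
  implemented; factorial and longitudinal designs are out of scope.
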