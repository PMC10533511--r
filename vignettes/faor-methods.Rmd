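---
title: "Methods: fetal abdominal overgrowth ratios, screening cascade, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fetal abdominal overgrowth ratios, screening cascade, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faor)
```

This vignette is the package's account of its science: the quantities it
computes, the assumptions behind them, the parameters a user might touch,
and the choices made where the design was genuinely open.

## The overgrowth ratios

At a routine scan, three biometry measurements — biparietal diameter
(BPD), abdominal circumference (AC) and femur length (FL), each in mm —
are converted into ultrasound-estimated gestational ages (GA-BPD, GA-AC,
GA-FL, in days) by inverting a growth chart: a reference table mapping
gestational age to the population-median measurement. With GA-LMP the
actual gestational age by the last menstrual period, the three fetal
abdominal overgrowth ratios are

$$\mathrm{FAOR}_{LMP} = \frac{GA\text{-}AC}{GA\text{-}LMP}, \qquad
  \mathrm{FAOR}_{BPD} = \frac{GA\text{-}AC}{GA\text{-}BPD}, \qquad
  \mathrm{FAOR}_{FL} = \frac{GA\text{-}AC}{GA\text{-}FL}.$$

Each is dimensionless, invariant to the unit of gestational age, and equal
to 1 under perfectly proportionate growth. The LMP ratio corrects for scan
timing; the BPD and FL ratios isolate abdominal growth relative to head
and femur. Fetal abdominal obesity (FAO) is defined empirically: a ratio
at or above the analysed cohort's 90th percentile (inclusive).

Why a ratio of *gestational ages* rather than of raw measurements: the
chart inversion places every measurement on a common, clinically
interpretable scale, so a ratio of 1.08 at 26 weeks reads directly as
"the abdomen measures two weeks ahead". The approach assumes only that
the chart is strictly monotone over its valid range — all analyses are
chart-agnostic in the sense that no published chart coefficients enter
any computed result.

### Growth-chart evaluation and inversion

Charts are tabulated, not analytic, so the forward curve is the linear
interpolant of the knots (exact at knots, monotone between them) and the
inverse is found by bisection on that interpolant with a tolerance of
1e-3 day — about five orders of magnitude below clinical resolution, and
cheap because the bisection is vectorised. The shipped charts are
synthetic: weekly knots from 14 to 43 weeks tabulated from smooth
monotone quadratics in the physiological range of each measurement
(`biometry_curve()`). They stand in for whichever national reference a
site uses; `chart.path.{bpd,ac,fl}` swaps in any two-column CSV. The tests
assert the chart-agnostic properties (round-trip error below 0.01 day,
strict monotonicity of the inverse) rather than any coefficient value.

A measurement outside the chart's value range is *unconvertible*: the
pipeline flags the record and drops it from ratio analyses with a logged
reason, rather than extrapolating or failing silently. Estimated fetal
weight uses the polynomial form $1.07\,\mathrm{BPD}^3 +
0.30\,\mathrm{AC}^2\,\mathrm{FL}$ (cm in, grams out); both coefficients
are configuration keys (`efw.*`) because several published formulas share
this shape.

## The screening cascade and the NGT cohort

Glycemic status follows the two-step design: a universal 50-g glucose
challenge test (GCT) at 24–28 weeks, then a 3-h 100-g OGTT for women at
or above the 140 mg/dL screen threshold. OGTT values are compared
inclusively to the Carpenter–Coustan thresholds (fasting/1 h/2 h/3 h =
95/180/155/140 mg/dL, keys `cc.*`): two or more exceedances diagnose
gestational diabetes, exactly one is a one-value abnormality, zero is
normal glucose tolerance (NGT). A screen-positive woman with no OGTT is
unclassifiable. All thresholds are inclusive ≥, matching the usual
statement of the criteria; the boundary behaviour is pinned by tests.

The exclusion cascade applies, in order: hypertension before 24 weeks,
missing maternal weight record, missing GCT, then the glycemic removals
(unclassifiable, one-value, GDM), then delivery elsewhere. The order
matters for the per-stage counts (a record with two disqualifying
features is counted at the first), so the log telescopes exactly:
each stage's `n_in` equals the previous stage's `n_out`, and the last
`n_out` is the analysis cohort. `screening_flow_counts()` runs the same
telescoping on pre-tabulated stage counts, which is how published cohort
flows are checked without patient-level data.

Subgroups cross maternal age with pre-pregnancy BMI at the conventional
risk boundaries, both inclusive: G1 (< 35 y, < 25 kg/m²), G2 (< 35,
≥ 25), G3 (≥ 35, < 25), G4 (≥ 35, ≥ 25). HOMA indices use the HOMA1
closed forms $G\cdot I/405$ and $360\,I/(G-63)$; the secretion index is
returned missing at or below 63 mg/dL where its denominator is singular.
LGA at birth is a weight at or above the sex- and completed-week-matched
90th percentile of a reference table; macrosomia is ≥ 4000 g
(`macrosomia.cutoff_g`).

## Statistical battery

* Pairwise subgroup comparisons use Welch's t test by default. The
  subgroups are wildly unbalanced (the obese groups are ~3% each of the
  cohort) with no reason to assume equal variances; the pooled test is
  available by flag. Family size for Bonferroni correction defaults to 6
  (all pairs of four groups); the correction is multiply-and-cap, which
  preserves the ordering of p values.
* Categorical outcomes use the pooled two-proportion z test without
  continuity correction, with a Wald (unpooled) CI on the risk
  difference. Its exact size at n = 200/arm and p = 0.2 is 0.0508 (by
  full binomial enumeration), and the tests check both the simulated size
  and agreement with an unconditional exact enumeration oracle at small n.
* Crude odds ratios are the 2×2 cross-product with the Woolf log-scale
  CI; any zero cell triggers the Haldane–Anscombe +0.5 correction on all
  cells and is flagged. Model-based odds ratios come from maximum-
  likelihood logistic fits with Wald CIs; a single-binary-exposure fit
  must and does reproduce the crude OR to 1e-6, which the tests use as an
  oracle identity. Quasi-complete separation is detected (non-convergence
  or runaway coefficients) and reported as a flagged row instead of a
  spurious estimate.
* Adjusted odds ratios by subgroup drop any adjustment covariate that
  defines the exposure: the default set is {maternal age, pre-pregnancy
  BMI, weight gain to the screening visit, GCT glucose}
  (`adjust.covariates`), from which age and BMI are removed automatically
  when the exposure is the age × BMI subgroup. The report echoes the
  resolved set.
* All tests are two-sided at α = 0.05; complete-case analysis per cell,
  with every percentage cell carrying its own numerator and denominator.
  This is deliberate: published tables of this design often have
  per-cell denominators smaller than the group size (missing biochemistry,
  missing biometry), and a report that stores only percentages cannot be
  audited. Rendering uses half-up rounding — one decimal for percentages,
  two for odds ratios — because that is the convention of clinical
  tables; `round_half_up()` exists because base R rounds half to even.

### FAO classification choices

The empirical cutoff uses linear interpolation between order statistics
(the type-7 convention) — a specific, documented choice among the many
quantile definitions; the tests verify it against a sort-based oracle to
1e-12. Classification is inclusive at the cutoff. On continuous data the
cohort self-classifies at 10% within 1/n by construction.

Two open choices are resolved as configuration with defaults:

* **Headline criterion.** Outcome analyses need a single FAO flag while
  three ratios exist. The default headline is the GA-AC/GA-LMP criterion —
  it is the scan-timing-corrected ratio and the one whose prevalence
  matches single-ratio reporting in cohorts of this design — and
  `fao.headline` can select any single ratio or the union.
* **Near-term thresholds.** By default the near-term scan is classified
  against the cutoffs derived at 24–28 weeks (persistence of the same
  definition); `fao.rederive_near = TRUE` re-derives them from near-term
  ratios instead. Whether re-derivation is more appropriate depends on
  whether one reads "90th percentile" as a fixed definition or a
  per-visit one; both are defensible, so both are implemented.

## The synthetic cohort generator

The generator exists so that every stage of the pipeline is testable with
*known* answers. It emulates, with configurable parameters:

* the four-subgroup mixture (defaults 63/3/31/3%), with truncated-normal
  age and BMI within groups respecting the subgroup boundaries;
* a planted linear model of the mid-gestation LMP ratio on age, BMI,
  weight gain and GCT glucose (defaults sized so the ratio has mean
  ≈ 1.028 and SD ≈ 0.04, and the older groups run ≈ 0.005–0.01 higher);
* biometry produced by the *forward* growth charts: the abdominal GA is
  `GA-LMP × FAOR`, AC is the chart median there plus Gaussian measurement
  noise (default SD 1.5 mm), and BPD/FL are generated at `GA-LMP` times a
  head-scale factor ~N(1.018, 0.030) — scans systematically read slightly
  ahead of menstrual dating, which is what makes the BPD/FL-denominated
  ratios centre near 1.010 while the LMP ratio centres near 1.028;
* the screening cascade with planted, mutually exclusive exclusion
  categories whose OGTT panels are drawn truncated so the planted
  category *provably* survives re-classification;
* logistic outcome links from subgroup and true FAO status to LGA,
  macrosomia and primary cesarean delivery (default subgroup ORs
  1/3.0/1.5/2.8, 1/2.5/0.95/1.1 and 1/1.3/1.35/1.3; FAO effects 4.5,
  4.5, 1.35). LGA and macrosomia are coupled through a shared uniform
  with the macrosomia probability capped by the LGA probability, so
  macrosomia implies LGA, both marginal odds ratios hold exactly, and
  birth weights can be drawn consistently with both the 90th-percentile
  reference and the 4000-g cutoff.

`planted_truth()` returns what the pipeline should recover. The outcome
ORs and the ratio-model coefficients are configured directly; the
marginal per-subgroup FAO odds ratios are derived semi-analytically by
propagating truncated-normal moments through the linear model and solving
the mixture quantile for the population cutoff. That derivation treats
the within-group ratio as Gaussian; since age and BMI are truncated
normals the tail probabilities carry a small skew error (below 0.01 in
probability at the defaults), which the tests acknowledge by checking
absolute agreement at that resolution against a 200,000-record
simulation.

What the generator does **not** emulate: longitudinal growth between the
two scan snapshots, twin pregnancies, treatment effects, differential
missingness (biometry availability is independent of covariates),
heavier-tailed measurement error, or an association between fetal sex
and overgrowth. Passing tests therefore demonstrate that the pipeline's
statistics are calibrated and its transformations correct under a clean
data-generating process — not that any clinical association estimated
from real data is unbiased with respect to these unmodelled features.

### Calibration check

The end-to-end recovery test generates 20 cohorts of n = 20,000 under
fixed seeds, runs the complete pipeline (exclusions → GA estimation →
ratios → cutoffs → classification → models), fits the *generating* model
(outcome ~ subgroup + detected FAO) for each outcome, compares crude
detected-FAO odds ratios per subgroup with the semi-analytic planted
values, and requires at least 90% of all planted ORs across replicates to
lie inside their fitted 95% CIs. The pooled criterion is used because a
per-OR rule at 20 replicates cannot separate a calibrated estimator from
a broken one: with nominal 95% coverage, a single OR misses 3 or more of
20 replicates with probability above 7%, so some OR "fails" more often
than not even when everything is correct, while pooled coverage over 240
checks is stable. Detected-FAO misclassification from biometry noise is
about 2% and introduces no material bias (measured log-OR bias ≤ 0.2 SE).

## Numerical and degenerate-input policy

* GA is handled in decimal days internally; week-denominated inputs are
  converted as weeks × 7. Lengths are mm; EFW converts to cm internally.
* Bisection tolerance 1e-3 day; round-trip error in practice ~2e-4 day.
* Identical constant samples in a t test return a defined (0, p = 1)
  result; two distinct constant samples are an error.
* Fewer than 10 finite ratios abort cutoff derivation; the pipeline then
  falls back to the fixed external cutoffs (1.080/1.071/1.069).
* An empty cohort (or one fully excluded) produces a complete exclusion
  log and an empty report rather than an error.
* Non-finite ratios are dropped from cutoff derivation with a logged
  count; unconvertible biometry is flagged per record.

## Problem sizes in the test-suite

Simulation-based tests run at sizes chosen to keep Monte-Carlo noise well
below the asserted tolerances while the whole suite stays fast: null
size at 2000 replicates, CI coverage at 1000 replicates, self-
classification at n = 5000, semi-analytic moment checks at n = 200,000
(one draw), and pipeline recovery at 20 × n = 20,000. Linear-coefficient
bias is averaged over 20 replicate fits because a single fit's sampling
error is the same order as the 10%-of-effect bound being asserted.

## Limitations

The shipped charts and birth-weight reference are synthetic; results on
real cohorts require the site's own references. The exclusion cascade is
strictly ordered, so stage counts are not invariant to reordering.
Logistic CIs are Wald-based, which undercovers for very sparse cells
(separation is flagged but near-separation is not); profile-likelihood
intervals are out of scope. The one-value-abnormality group is excluded
from the NGT cohort rather than analysed separately.
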