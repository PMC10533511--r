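# faor

Fetal abdominal overgrowth ratios and perinatal outcome analysis for
pregnancy cohorts with normal glucose tolerance (NGT).

## The problem

Fetal overgrowth driven by the intrauterine metabolic environment tends to
show first in the abdomen: fat and liver glycogen accrue around the fetal
trunk, so the abdominal circumference (AC) runs ahead of the head and long
bones. A practical screen for this *fetal abdominal obesity* (FAO) compares
the ultrasound-estimated gestational age of the abdomen with other
gestational-age estimates at the routine 24–28-week visit:

- **GA-AC / GA-LMP** — abdominal GA over the actual GA by the last
  menstrual period, correcting for variation in scan timing;
- **GA-AC / GA-BPD** and **GA-AC / GA-FL** — abdominal GA over the GA
  estimated from the biparietal diameter and femur length, detecting
  overgrowth of the abdomen relative to head and femur.

Each *fetal abdominal overgrowth ratio* (FAOR) is dimensionless and equals
1 for perfectly proportionate growth. FAO is a ratio at or above the
cohort's empirical 90th percentile. The package implements the full
analysis pipeline around that statistic for epidemiologists studying risk
stratification in pregnancies that screen *normal* on glucose tolerance:

1. **Growth-chart inversion** (`load_growth_chart()`, `estimate_ga()`):
   monotone GA → median-biometry reference tables, evaluated by linear
   interpolation and inverted by bisection to turn a measured BPD/AC/FL
   (mm) into an estimated GA (days); estimated fetal weight by the
   polynomial `EFW = 1.07·BPD³ + 0.30·AC²·FL` (cm → g, coefficients
   configurable).
2. **Screening cascade** (`classify_glycemic_status()`,
   `apply_exclusions()`): universal 50-g glucose challenge test (GCT,
   screen-positive ≥ 140 mg/dL) followed by a 3-h 100-g OGTT classified by
   the Carpenter–Coustan thresholds (95/180/155/140 mg/dL, inclusive; ≥ 2
   exceedances = gestational diabetes, 1 = one-value abnormality), plus the
   ordered exclusion flow that defines the NGT cohort, with a telescoping
   per-stage log.
3. **FAOR classification** (`compute_faors()`, `empirical_thresholds()`,
   `classify_fao()`): empirical type-7 quantile cutoffs derived from the
   analysed cohort (or fixed external cutoffs 1.080/1.071/1.069), inclusive
   classification, configurable headline criterion.
4. **Outcome statistics** (`two_sample_t()`, `proportion_test()`,
   `crude_or()`, `fit_logistic_or()`, `fit_linear()`, `pearson_corr()`,
   `bonferroni_adjust()`): pairwise Welch t tests and pooled two-proportion
   z tests with Bonferroni correction, Haldane-corrected cross-product odds
   ratios with Woolf CIs, and adjusted odds ratios from maximum-likelihood
   logistic fits with Wald CIs.
5. **Synthetic cohorts with planted truth** (`generator_config()`,
   `generate_cohort()`, `planted_truth()`): a generator that emulates the
   age × BMI subgroup structure (G1 young/non-obese … G4 older/obese, with
   35 years and BMI 25 kg/m² as inclusive boundaries), plants a linear
   model for the mid-gestation FAOR on clinical factors and logistic links
   from subgroup and FAO status to large-for-gestational-age birth (LGA),
   macrosomia (≥ 4000 g) and primary cesarean delivery, and reports the
   implied ground truth for parameter-recovery testing.
6. **Reporting** (`run_study()`, `render_report()`): end-to-end runs
   producing clinical-style tables in which every percentage cell carries
   its numerator and denominator, rendered as text, full-precision JSON or
   CSV.

## Worked example

```r
library(faor)

cfg    <- generator_config(n = 5000, seed = 42)
cohort <- generate_cohort(cfg)
report <- run_study(cohort)
print(report)
```

```
<faor_report: 5000 records in, 4240 included, 3189 with mid-gestation biometry>
<fao_thresholds: level 0.90 | GA-AC/GA-LMP >= 1.0779, GA-AC/GA-BPD >= 1.0801, GA-AC/GA-FL >= 1.0820 | n_ref 3189/3189/3189>
Exclusion log:
                 stage n_in n_excluded                                      reason n_out
                   pih 5000         16 pregnancy-induced hypertension before 24 GW  4984
      no_weight_record 4984         23                   no maternal weight record  4961
                no_gct 4961        146                          no 50-g GCT result  4815
               no_ogtt 4815         33  GCT-positive without OGTT (unclassifiable)  4782
 one_value_abnormality 4782        169           one OGTT value at/above threshold  4613
                   gdm 4613        257    gestational diabetes (Carpenter-Coustan)  4356
   delivered_elsewhere 4356        116               delivered at another hospital  4240
```

Of 5000 simulated pregnancies, 4240 form the NGT analysis cohort and 3189
have convertible mid-gestation biometry; the derived 90th-percentile FAOR
cutoffs are printed with their reference-set sizes. FAO prevalence by
subgroup, with explicit denominators:

```r
cells <- report$table3$cells
cells[cells$variable == "FAO at diagnosis", c("group", "k", "n", "pct")]
```

```
 group   k    n  pct
 Total 319 3189 10.0
    G1 152 1999  7.6
    G2  11   95 11.6
    G3 141 1002 14.1
    G4  15   93 16.1
```

Self-classification pins the total at 10.0% by construction; the
older-age groups (G3, G4) show the elevated prevalence the generator
plants. Adjusted odds ratios for LGA at birth (vs G1), in the
conventional two-decimal `OR (low, high)` format:

```r
t5 <- report$table5[report$table5$outcome == "lga", ]
format_or_ci(t5$estimate, t5$ci_low, t5$ci_high)
#> "3.79 (2.21, 6.50)"  "1.84 (1.40, 2.43)"  "5.51 (3.39, 8.97)"
```

`render_report(report, "text" | "json" | "csv", path)` writes the whole
report; JSON output is byte-identical across reruns on the same input.

## Package data

All shipped reference tables are synthetic and labelled as such in their
filenames: weekly growth-chart tables for BPD/AC/FL (14–43 weeks,
`inst/extdata/chart_*_synthetic.csv`) tabulated from smooth monotone
curves, and a sex- and week-specific 90th-percentile birth-weight table
(`inst/extdata/lga_p90_synthetic.csv`). Any published reference in the
same CSV schema can be swapped in through the configuration
(`chart.path.*`, `lga.reference_path`); every analysis is chart-agnostic
and relies only on monotonicity. See `vignette("faor-methods")` for the
model, assumptions and design decisions.
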