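# uroscreen

Diagnostic-accuracy toolkit for automated urine-culture screening.

Clinical microbiology laboratories culture hundreds of urine samples a
day, and most plates come back negative. Automated urinalysis analysers
(urine flow cytometers, flow-imaging microscopes) report bacteria and
leukocyte concentrations (counts/µL) within minutes, and a well-chosen
cut-off rule can *screen out* culture-negative samples before a plate is
ever poured. `uroscreen` is for laboratory scientists and biostatisticians
evaluating such analysers against urine culture as the gold standard.

## What it computes

With culture truth defined as growth ≥ a CFU/mL threshold (default 10⁵;
contaminated cultures counted as negative), the package provides:

* **Empirical ROC and AUC** per count channel, with thresholds drawn from
  the observed values (screen-positive ⇔ count ≥ cut-off); the
  trapezoidal AUC equals the Mann–Whitney statistic
  P(X₊ > X₋) + ½ P(X₊ = X₋).
* **Cut-off optimization**, single-marker and combined. The combined rule
  is the screening-lab form *bacteria ≥ t_b OR WBC ≥ t_w*, optimized by
  exhaustive product-grid search under either the Youden index
  (Se + Sp − 1) or a **sensitivity floor** (maximize Sp subject to
  Se ≥ 0.95, the guideline-driven default), plus the full Pareto front of
  non-dominated (Se, Sp) pairs.
* **Accuracy metrics with uncertainty**: Se, Sp, PPV, NPV, accuracy,
  prevalence, and the culture-workload **reduction** (TN + FN)/N, with
  Wilson score intervals; the Bayes identities
  PPV = Se·p / (Se·p + (1−Sp)(1−p)) etc. are exposed directly and double
  as an audit of published accuracy tables.
* **Two-device comparison at matched sensitivity**, with seeded bootstrap
  percentile intervals for the specificity and reduction differences.
* **A calibrated synthetic cohort generator**: log-normal
  class-conditional counts whose AUC is set in closed form
  (AUC = Φ(Δµ/√(σ₋² + σ₊²))), with built-in device profiles emulating a
  flow-cytometry-class analyser (bacteria AUC 0.943, cut-off scale
  ~138/µL) and a flow-imaging-class analyser (AUC 0.864, scale ~5.7/µL).

## Worked example

```r
library(uroscreen)

# a 1220-sample cohort at 17.4% expected culture positivity
cohort <- generate_cohort(generator_config(n = 1220, seed = 1))
cohort
#> <urine_cohort> 1220 samples (199 culture-positive, 60 contaminated) | truth at 1e+05 CFU/mL

# best combined rule keeping sensitivity at or above 95%
optimize_dual(cohort, criterion = "se_floor", se_target = 0.95)
#> <dual_opt> criterion: se_floor (se >= 0.95)
#> <dual_rule> bacteria >= 187.9972/uL OR WBC >= 922.0575/uL
#> <metric_set> SE 95.5% | SP 79.6% | PPV 47.7% | NPV 98.9% | ACCURACY 82.2% | REDUCTION 67.4%
#>   prevalence: 16.3%
```

Read: on this cohort the screen can skip 67.4% of cultures (`REDUCTION`)
while missing 4.5% of culture-positives (SE 95.5%), and a screen-negative
report is right 98.9% of the time (NPV). The audit direction works from
published summary numbers alone — feeding a reported combined operating
point (Se 95.3%, Sp 70.4%) and prevalence 213/1220 through the Bayes
identities recovers the predictive values such a table should print:

```r
rates_to_predictive_values(0.953, 0.704, 213/1220)
#> <metric_set> SE 95.3% | SP 70.4% | PPV 40.5% | NPV 98.6% | ACCURACY 74.7% | REDUCTION 58.9%
#>   prevalence: 17.5%
```

A thin CLI wrapper (`inst/cli/uroscreen`) exposes `simulate`, `roc`,
`optimize`, `evaluate` and `compare` subcommands over the same functions.
See `vignette("urine-screening-methods")` for the models, calibration
details and design decisions.

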