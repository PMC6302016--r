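---
title: "Screening urine samples out of culture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening urine samples out of culture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uroscreen)
```

## The problem

Urine culture is the gold standard for diagnosing urinary tract infection,
but every culture costs a plate, incubator space and a day of waiting, and
in a typical hospital laboratory more than half of the plates come back
negative or contaminated. Automated urinalysis analysers (urine flow
cytometers and flow-imaging microscopes) report bacteria and leukocyte
particle concentrations in counts/uL within minutes. A *screening-out*
rule uses those counts to declare samples culture-negative up front: only
screen-positive samples are cultured. The two quantities that matter are
the rule's **sensitivity** against culture (a missed culture-positive is a
missed infection, so guidelines ask for 90--95% or better at the
10^5^ CFU/mL bacteriuria threshold) and the **reduction**: the fraction of
samples screened out, `(TN + FN) / N`, which is workload saved.

`uroscreen` implements the complete evaluation of such rules against
culture, and a calibrated synthetic cohort generator so that every stage of
the pipeline is testable without access to patient data.

## Ground truth

A culture is labelled positive when growth reaches `cfu_threshold`
(default 10^5^ CFU/mL, inclusive; 10^4^ is a configuration knob, not a
separate code path, because evaluations commonly report both). Cultures
growing three or more distinct colony types are *contaminated*; they are
kept in the cohort and counted as truth-negative by default
(`contaminated_is_negative = TRUE`), because a screening evaluation has to
account for every submitted sample and a mixed-flora plate yields no
pathogen identification. Setting the flag to `FALSE` moves them to the
positive class for sensitivity analyses. Samples with missing counts are
rejected at read time rather than zeroed; pre-analytical quality
exclusions are modelled only as an optional `qc_excluded` column that the
reader drops and logs -- the package makes no attempt to infer sample
quality from the counts themselves.

## ROC analysis and cut-off selection

All thresholds are *flag at or above* levels: a sample screens positive
when its count is `>=` the cut-off. Candidate cut-offs are the observed
values themselves plus a `+Inf` sentinel, not midpoints between values, so
every reported cut-off is a reading the analyser can actually produce.
The empirical ROC curve has one operating point per distinct value; tied
values collapse to a single point, and the trapezoidal AUC then equals the
Mann--Whitney statistic P(X~pos~ > X~neg~) + ½ P(X~pos~ = X~neg~) exactly
(the package's test suite checks this identity against exhaustive pair
counting).

Two cut-off criteria are provided:

* **`se_floor`** (default, target 0.95): maximize specificity subject to
  sensitivity at or above the target. This operationalizes "the most
  balanced cut-off" as screening practice understands it -- guidelines
  anchor on sensitivity above 90--95%, and the reported combined rules of
  both analyser generations sit at about 95% sensitivity.
* **`youden`**: maximize Se + Sp − 1, the classical balance index.

Ties are broken deterministically: higher sensitivity first, then the
higher cut-off (the stricter rule, which flags fewer samples at equal
performance). All comparisons are made on integer confusion-cell counts,
never on floating-point rates, so tie-breaking is exact.

## The combined OR rule

The combined screen is `bacteria >= t_bac OR wbc >= t_wbc`. The
leukocyte channel rescues culture-positive samples whose organisms the
bacteria channel undercounts (yeasts and swarming or aggregating rods are
the classical examples), at the price of specificity. `optimize_dual()`
searches the full product grid of candidate pairs -- no pruning heuristics
-- with incremental confusion updates: sweeping the bacteria grid top-down,
each sample leaves the per-WBC-bin tallies when the bacteria channel
catches it, so each grid row costs one cumulative sum and the whole search
is O(|grid~bac~| · |grid~wbc~|). At cohort sizes of a few thousand this is
a few million updates, interactive on a desktop. The same sweep collects
the Pareto front of non-dominated (Se, Sp) pairs. An `"and"` combiner
exists on `apply_rule()` for completeness but is not a reported screening
form and is not part of the optimizer's contract.

Setting one channel's grid to `Inf` (e.g. `wbc_grid = Inf`) degrades the
search to the single-marker case and reproduces `best_single_cutoff()`
exactly, tie-breaks included -- a property the test suite verifies.

## Metrics

`metrics_from_confusion()` computes Se, Sp, PPV, NPV, accuracy, prevalence
and reduction at full precision; percentages are rounded half-up to one
decimal only in the report layer. Denominator-zero metrics are returned as
`NA` with an explicit `undefined` flag, never as 0. The Bayes identities
in `rates_to_predictive_values()`,

$$PPV = \frac{Se\,p}{Se\,p + (1-Sp)(1-p)}, \qquad
  NPV = \frac{Sp\,(1-p)}{Sp\,(1-p) + (1-Se)\,p},$$
$$reduction = Sp\,(1-p) + (1-Se)\,p, \qquad
  accuracy = Se\,p + Sp\,(1-p),$$

are algebraically identical to the confusion-matrix forms and double as an
audit tool for published accuracy tables when the underlying per-sample
data are unavailable: feeding a printed (Se, Sp) pair and the cohort
prevalence through them recovers the printed PPV/NPV/reduction cells if
and only if the table is internally consistent. PPV and NPV default to the
empirical cohort prevalence; an override exists for external-prevalence
what-ifs. Wilson score intervals (via `stats::prop.test` without
continuity correction) accompany every proportion in evaluation reports.

One instructive audit: for the flow-cytometry device's published combined
operating point (Se 95.3%, Sp 70.4%, prevalence 213/1220), the identities
give a reduction of about 58.9%, while the published figure is 58.3% --
a discrepancy of under one percentage point whose origin (possibly a
different denominator) is not stated in the source. The package documents
this in a test rather than resolving it.

```{r bayes-audit}
rates_to_predictive_values(0.953, 0.704, 213 / 1220)
```

## The synthetic cohort generator

No per-sample data accompany published analyser evaluations, so the
generator produces cohorts with the statistical structure the analysis
assumes. Design choices, made once and fixed:

* **Log-normal class-conditional counts.** Particle counts are
  non-negative and strongly right-skewed; on the natural-log scale each
  channel is Gaussian within each culture class, which makes the channel's
  AUC available in closed form,
  $AUC = \Phi\!\big((\mu_{pos}-\mu_{neg})/\sqrt{\sigma_{neg}^2+\sigma_{pos}^2}\big)$,
  and therefore lets a target AUC be *calibrated exactly*
  (`calibrate_separation()` is the closed-form inverse; the round trip is
  tested to 1e-10).
* **Anchored operating scale.** `calibrated_channel()` fixes
  $\mu_{pos} = \log(c) + \Phi^{-1}(0.95)\,\sigma_{pos}$ so that the
  population 95%-sensitivity cut-off sits at a chosen count $c$. The
  built-in `"UF1000i"` profile targets bacteria AUC 0.943 / WBC AUC 0.832
  with cut-offs anchored at 138 and 119.8 counts/uL; `"FUS200"` targets
  AUCs 0.864 / 0.834 with a shared scale shift of −log(138/5.7) ≈ −3.19,
  emulating two devices that see the same biology on count scales about
  25-fold apart. These four AUCs and two scales are *calibration inputs*
  taken from published figure captions; everything else about the
  distributions is this package's own modelling choice and is labelled as
  such.
* **Unit log-scale sigmas** in both classes (geometric SD ≈ 2.7, a
  realistic dispersion for urine particle counts) and a within-class
  log-count correlation `rho = 0.3` between the channels: bacteriuria and
  pyuria co-occur, but far from deterministically. The correlation is a
  property of the channel *pair*, so it lives on the device profile rather
  than on either channel model.
* **Prevalence 213/1220 ≈ 17.4%** and default `n = 1220`, the composition
  of a mixed inpatient/outpatient evaluation window; **contamination**
  defaults to 5% of truth-negatives (no published rate exists; the value
  is a documented, freely configurable default), with log-means midway
  between the class means -- mixed-flora plates look neither cleanly
  negative nor cleanly positive on the analyser.
* **Colony counts** consistent with the class by construction:
  log10-uniform on [5, 7.5] for positives, [0, 5) for negatives, so truth
  labelling is exact at the 10^5^ threshold and configurable thresholds
  below it remain meaningful.
* **Per-sample substreams.** Sample *i* draws from a seed derived from
  (seed, *i*), so one seed fixes the cohort bit-for-bit and growing `n`
  appends samples without reshuffling earlier ones.

What the generator deliberately does **not** emulate: organism-specific
count signatures (the swarming-*Proteus* / yeast false-negative pattern),
instrument carry-over, mucus interference, or any fitting of parameters to
real instrument exports. Passing tests therefore demonstrate that the
*pipeline* is correct under the stated statistical assumptions, not that
any particular analyser achieves these numbers on real specimens.

With contamination in the negative class, the realized bacteria AUC falls
slightly below the clean-channel calibration target (about 0.935 against
0.943 at the defaults) because contaminated negatives carry elevated
counts; the parameter-recovery tests use a ±0.02 band around the target,
which covers both this composition effect and Monte-Carlo noise at
n = 5000.

## Device comparison

`compare_devices()` mirrors how screening studies compare analysers: not
at matched thresholds (meaningless across count scales) but at **matched
sensitivity** -- each device is optimized independently under
`se_floor(se_target)` and the specificities and reductions are read off
side by side. Because published evaluations of this kind report no
uncertainty, the package adds seeded bootstrap percentile intervals for
the Sp and reduction differences: samples are resampled with replacement
within each cohort and the metrics recomputed at the *fixed* optimized
rules (re-optimizing inside the bootstrap would mix rule-selection
variability into an interval meant to describe the chosen rules; the
fixed-rule form is the standard operating-point bootstrap). Default 1000
resamples.

```{r compare, eval = FALSE}
uf  <- generate_cohort(generator_config(n = 1220, seed = 1))
fus <- generate_cohort(generator_config(
  n = 1220, seed = 2, device = default_device_profile("FUS200")))
compare_devices(uf, fus, se_target = 0.95)
```

## Numerical and degenerate-input conventions

* Culture boundary inclusive (`>=`), decimal separator `"."` only.
* ROC requires both classes; single-class truth is a contract error, as is
  an unachievable sensitivity floor (the error names the maximum
  achievable sensitivity).
* All criterion comparisons and tie-breaks on integer cell counts.
* `+Inf` thresholds are legal everywhere and serialize as the string
  `"Inf"` in JSON reports.
* Errors carry condition classes (`uroscreen_contract_error`,
  `uroscreen_format_error`, `uroscreen_io_error`); the CLI maps them to
  exit codes 2 and 3.

## Problem sizes used in the shipped checks

The test suite exercises the oracle equivalences (pair-counting AUC,
naive double-loop dual search, brute-force Pareto filtering) on hundreds
of random instances of up to 50 samples, where exhaustive enumeration is
exact and fast, and the parameter-recovery checks on generated cohorts of
n = 5000, where Monte-Carlo bands of ±0.02 (AUC) and ±0.05 (specificity at
the floor-constrained cut-off) are comfortably discriminating. The
acceptance script evaluates the two built-in device profiles at n = 5000
with a full product-grid optimization each.

## Known limitations

* Devices are modelled as separate cohorts; truly paired per-sample
  analyses (both analysers on aliquots of the same specimen) are not
  represented in the tabular dialect, so no paired tests (McNemar, DeLong)
  are offered.
* Rules over more than two channels, probabilistic channel combination,
  smoothed/binormal-fitted empirical ROC curves and AUC-difference tests
  are out of scope.
* The generator's distributional defaults are calibrated to published
  summary statistics, not fitted to instrument data; absolute metric
  values on real cohorts will differ even when the pipeline is exact.
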