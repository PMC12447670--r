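---
title: "Detecting sudden gains in session-by-session therapy measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sudden gains in session-by-session therapy measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suddenshifts)
```

## The construct and its operationalisation

Therapy does not always proceed gradually: a sizeable minority of clients
improve in a single large step between two adjacent sessions and then hold
that improvement. `suddenshifts` operationalises such *sudden gains* on
session-by-session outcome measures with the three Tang–DeRubeis criteria,
applied to every evaluable between-session interval (N, N+1):

1. **Absolute size.** The oriented improvement
   (`score(N) − score(N+1)` on lower-better scales,
   `score(N+1) − score(N)` on higher-better scales) must reach the
   measure's criterion-one cutoff, in scale points. Boundary equality
   passes: the criteria are "at least" thresholds throughout.
2. **Relative size.** The improvement must be at least a fraction
   (default 0.25) of the pregain level. On a lower-better symptom scale
   the pregain level is the raw score. On a higher-better scale a
   fraction of the raw score is not meaningful (a high score is a *good*
   state), so the package reflects it into the remaining deficit,
   `scale_max − score(N)`. With a zero base (score already at the ideal
   end) the criterion passes vacuously and criterion one decides.
3. **Stability.** The mean of the up to three observed scores after the
   candidate gain is compared with the mean of the up to three before
   (windows {N−2, N−1, N} and {N+1, N+2, N+3}, clipped to the series) by a
   pooled-variance two-sample *t* statistic, oriented so that positive *t*
   means improvement. The statistic must *exceed* the critical value for
   the observed per-side counts: 2.776 (3 + 3 scores, df 4), 3.182 (one
   score missing on one side, df 3), 4.303 (one missing on each side,
   df 2). These are the two-sided 5% Student-*t* quantiles at the
   corresponding degrees of freedom, stored as the printed three-decimal
   constants and fully configurable via `detection_config()`.

Sudden *losses* are the same definition run in the deterioration
direction; internally the measure's direction is flipped, which yields
exactly the mirrored criteria (worsening versus the cutoff, worsening
versus the reflected base, *t* in the worsening direction). A shift is
*reversed* when any later observed session has moved back toward the
pre-shift level by at least `reversal_fraction` (default 0.5) of the
shift's magnitude; the earliest such session is recorded.

### Missing sessions

Missing responses are kept as explicit gaps at their true session indices
— series are never renumbered, because the detection windows depend on
real spacing — and are never imputed: imputation could manufacture gains
nobody reported. Consequences of this choice:

* An interval with a missing endpoint is *not evaluable*: it is neither a
  gain nor a non-gain, and is excluded from the denominator of analysed
  intervals.
* A stability window retaining fewer than `min_per_side` (default 2)
  observed scores also makes the interval not evaluable.
* The adaptive critical values above make maximal use of partially
  observed windows instead of discarding them.

### Degenerate windows

With zero pooled variance the *t* statistic is undefined; the package
takes the limit: any nonzero mean change in the candidate direction passes
(the statistic diverges), zero change fails. This matters in practice —
flat plateaus around a clean step are precisely the textbook sudden gain,
and they have zero within-window variance.

## Calibrating criterion one: the reliable change index

The cutoff should exceed what measurement error alone can produce.
`rci_threshold()` implements the Jacobson–Truax form
`1.96 · SD_baseline · √(2(1−r))` from the baseline standard deviation and
a reliability coefficient `r`; `cutoff_from_threshold()` rounds the result
*up* to the next whole number (scales record whole numbers; rounding up is
the conservative direction, and whole numbers are fixed points). A
reliability of exactly 1 is rejected rather than silently producing a zero
cutoff. No artificial minimum is imposed beyond the ceiling: thresholds in
(1, 2] all become 2-point cutoffs arithmetically. Since published
reliability coefficients vary by source (internal consistency versus
test–retest), the measure configuration records the chosen inputs, and a
direct `criterion1_cutoff` override is always possible.

## Eligibility

`apply_eligibility()` reproduces the analysis-population logic of a
pragmatic therapy trial: participants who withdrew consent (optional
`withdrew` covariate column) are removed first, then participants with
fewer than `min_sessions = 6` sessions received; series with fewer than 2
observed responses contribute nothing to a measure; and measures retained
by fewer than 21 participants are dropped entirely. The strict-inequality
readings ("more than one response", "more than 20 participants") are
implemented literally as ≥ 2 and ≥ 21. Every exclusion is logged with its
reason, and the operation is idempotent.

## Summaries

`summarize_measure()` builds the per-measure cohort row: participants
analysed, evaluable intervals, total gains, occurrence (participants with
≥ 1 gain), modal session of the first gain, multiples, pooled magnitude
mean (SD), and reversals among gainers. Three reporting choices were
genuinely open and are resolved as follows:

* **Modal session convention.** Literature is ambiguous about whether "the
  session a gain occurred in" means N or N+1, and with two pre-window
  points required a first *shift* session of 2 is impossible while a first
  *pregain* session of 2 is not. Both modes are therefore reported
  (`modal_first_shift_session`, `modal_first_pregain_session`), with modal
  ties reported in full, smallest first.
* **Reversal denominator.** Reversal percentages are computed over
  participants with at least one gain; "any gain reversed" is the default
  basis, with "first gain reversed" available
  (`reversal_basis = "first"`).
* **Interval denominator.** "Intervals analysed" counts intervals with
  both endpoints observed (the looser reading);
  `stability_evaluable = TRUE` restricts to intervals whose windows also
  support the stability test.

Percentages and magnitude statistics are rounded to two decimals in the
summary tables; undefined statistics (no gains; SD of one gain) are `NA`
rather than zero.

## Association models

`fit_gain_logistic()` regresses "≥ 1 sudden gain on the measure" on the
adjustment set — sex, age group, ethnicity (white versus other), autism
spectrum disorder, intellectual disability, caregiver employment, primary
disorder (disruptive behaviour versus anxiety/depression, the latter as
reference), total sessions, and the pretreatment score on the measure —
reporting Wald 95% CIs on the log-odds scale, exponentiated, with
two-sided p values at the 5% level. Complete or quasi-complete separation
and non-convergence raise errors naming the offending term rather than
returning absurd intervals. `fit_final_score_model()` and
`fit_followup_model()` report unadjusted and adjusted mean differences for
gainers versus non-gainers (the follow-up model additionally adjusts for
the baseline SDQ total). Missing covariates are handled complete-case per
model with logged exclusion counts; no multiple-testing correction is
applied.

Cohen's *D* standardises a mean difference by the pooled observed outcome
SD across the two gain groups,
`s_p = sqrt(((n1−1)s1² + (n2−1)s2²)/(n1+n2−2))`, with the sign following
the mean difference as supplied. Published work is not consistent about
whether the adjusted or unadjusted difference is standardised, nor about
sign orientation on lower-better scales, so the package computes *D* for
both model rows and leaves orientation to the reader.

## The synthetic cohort generator

`simulate_cohort()` generates the data structure the analysis assumes:

* trajectories `clamp(baseline + trend·t + step·1[t ≥ N+1] + noise)` to
  the scale bounds, rounded to the measure's granularity (1 point for
  ordinal scales, 0.1 for the fractional mean-of-goals scale);
* an instantaneous planted step between sessions N and N+1 — matching the
  sudden-gain construct — with noise suppressed on a plateau of
  `plateau_length` (default 3) sessions each side of the step;
* gain planting via a logistic model on participant covariates, whose
  prevalences mirror a paediatric long-term-condition therapy cohort
  (about half female, three quarters white, 42% with intellectual
  disability, 10–28 sessions);
* missing-completely-at-random session gaps at `missing_rate`
  (default 0.15);
* a follow-up outcome linked linearly to gain status and baseline
  severity, and optionally a model-generated end-of-treatment score.

Identical `(config, seed)` pairs give byte-identical CSV exports.

The generator deliberately does **not** emulate informative dropout,
therapist effects, autocorrelated noise, or gradual (multi-session)
gains; passing tests on this generator therefore demonstrate correctness
of the detection arithmetic and estimation machinery under the stated
data-generating process, not robustness to every failure mode of real
routine-outcome data. Cohorts with a linear improvement trend and no
planted steps serve as the false-positive stressor.

**Recovery denominators.** The truth table flags a planted gain as
`detectable` when, after missingness, both anchor sessions are observed
and each stability window retains at least two scores. A gain whose
anchors were deleted cannot be identified by *any* method that refuses
imputation, so `evaluate_recovery()` reports recall over detectable
planted gains as the detector's figure of merit, alongside raw recall over
all planted gains and precision over all detections.

## Numerical and testing choices

* Detection is validated against an independent brute-force oracle
  (explicit window enumeration + `stats::t.test`) on randomized short
  series: 400 series in the routine suite and 10,000 in the acceptance
  checks, alongside a direction-symmetry property (reflecting a 0-based
  scale about its midpoint and flipping the direction label preserves all
  shifts; exact symmetry requires `scale_min = 0` because criterion two
  uses the raw pregain score).
* Truncating a series can legitimately *create* a gain by clipping a
  3-point post-window to a 2-point one (the statistic and critical value
  both change), so locality is asserted only for intervals whose windows
  the truncation does not touch.
* Monte-Carlo problem sizes: parameter recovery uses 200 replicate
  cohorts of 600 participants (logistic coefficient and adjusted mean
  difference, each required within two Monte-Carlo standard errors of
  truth); CI coverage uses 200 replicates of n = 2,000; recall/precision
  scenarios use 200-participant cohorts with 5-point steps, a 2-point
  cutoff and 3-session plateaus. These sizes give Monte-Carlo standard
  errors an order of magnitude below the effects being recovered.
* The clean-step recovery scenario places baselines well inside the scale
  bounds (mean 12, SD 2 on a 0–30 scale): a step that collides with a
  scale bound is truncated by clamping, which is a property of bounded
  scales, not a detector error.

## Limitations

Detection treats every interval independently; adjacent or overlapping
gains are all reported without pruning, and no alternative sudden-gain
definitions (percentage-only, effect-size-based) are provided beyond the
configurable constants. The stability test is directional by design —
"significantly different" is read in the direction of the candidate shift
— which is marginally more conservative than a two-sided reading for
shifts, and the quoted critical values are the two-sided quantiles. The
association models are standard GLM/OLS fits; with few gainers on a
measure the logistic model may legitimately refuse to fit (separation),
which the cohort-level wrapper records as a note rather than a crash.
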