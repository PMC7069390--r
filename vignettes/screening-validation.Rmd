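---
title: "Validating office blood-pressure screening against ambulatory monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating office blood-pressure screening against ambulatory monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Unattended automated office blood pressure (uAOBP) — three oscillometric
readings taken one minute apart with the patient resting alone, averaged —
is an attractive screening measurement because it suppresses the observer
effect. But screening decisions are ultimately judged against 24-hour
ambulatory monitoring (ABPM), the reference standard, and the two can
disagree in both directions: *white-coat* subjects are office-positive but
ambulatory-normal (false positives), *masked* subjects are office-negative
but ambulatory-hypertensive (false negatives). `abpmscreen` implements the
full validation workflow — raw cuff readings to a diagnostic-accuracy and
agreement report — together with a cohort simulator whose subjects carry
known latent phenotypes, so every stage of the pipeline can be checked
against ground truth.

## From readings to summaries

An ambulatory record is a sequence of timestamped systolic/diastolic pairs
over roughly 24 hours; the device inflates every 20 minutes during its
daytime window and every 40 minutes at night. Completeness quality control
follows the IDACO criteria: a record is usable only with at least 10
readings in the daytime analysis window (10:00–20:00) and at least 5 in
the nighttime window (00:00–06:00). Both windows are half-open
`[start, end)` — a reading stamped exactly 20:00 is *not* daytime — which
is unambiguous and matches common ABPM software. The same windows define
the daytime and nighttime means (plain arithmetic means of in-window
readings).

The 24-hour average must not over-weight the densely sampled daytime, so
each reading is weighted by the time interval it represents: from the
midpoint with its predecessor to the midpoint with its successor, the
first and last intervals clipped at the record's 24-hour span (fit time to
fit time + 24 h; later readings are discarded first). With equal spacing
this collapses to the arithmetic mean. Equivalently, it is the integral of
the nearest-reading step function over the span — the form the test suite
uses as an independent oracle. A `"hourly"` mode (mean of per-hour means),
another convention in device software, is available via
`weighted_24h_mean(mode = "hourly")`.

Office sessions are averaged over their valid readings (`sbp > dbp`, both
present). Three valid readings make a complete session; two are averaged
but flagged; fewer excludes the subject from the primary analysis. No
artefact rejection is applied to ambulatory readings by default — only
rows that are structurally impossible (`dbp >= sbp`, unparseable
timestamp) are dropped at ingest, with line numbers reported. Optional
plausibility bounds (SBP 60–260, DBP 40–160, pulse pressure ≥ 10 mmHg) can
be switched on.

## Phenotypes and accuracy

Screen positivity uses the guideline OR rule with non-strict inequalities
at three international cutoff pairs (≥130/80, ≥135/85, ≥140/90 mmHg), so
the positivity sets are nested and sensitivity must fall — and specificity
rise — as the cutoff tightens. The reference standards are 24-h mean
≥130/80 (confirmed hypertension), daytime mean ≥135/85 (awake
hypertension) and nighttime mean ≥120/70 (nocturnal hypertension); both
24-h and daytime references are exposed because published accuracy figures
differ depending on which is used. Crossing screen and confirmed status
yields the four-category phenotype (sustained / white-coat / masked /
normotensive), which partitions the analyzed subjects exactly and supplies
the 2×2 cells: sustained = TP, white-coat = FP, masked = FN,
normotensive = TN.

From the table: sensitivity, specificity, PPV and NPV as simple
proportions with Wilson score intervals by default (Wald and exact
Clopper–Pearson are available; the original analyses were run in a
package whose default is not stated, so the method is always recorded in
the output). Likelihood ratios use the delta-method CI on the log scale;
infinite or zero ratios are flagged, never truncated. AUROC is reported in
two labelled forms, because a single-cutoff study does not determine
which was used: the binary form `(sens + spec)/2` and the empirical
Mann–Whitney form on a continuous score (the signed margin to the cutoff
pair, `max(SBP - sbp_cut, DBP - dbp_cut)`), with a Hanley–McNeil CI.
McNemar's test is exact (two-sided binomial) when the discordant total is
below 25 and asymptotic `(b-c)^2/(b+c)` otherwise.

Agreement between devices is summarized by Bland–Altman: mean difference,
SD of differences (n−1), limits of agreement `bias ± 1.96·SD`, and the
Pitman–Morgan check for proportional error as the correlation between
difference and mean with a t-test on r. A multivariable OLS regression
asks whether age, sex, site, BMI, diabetes or smoking shift the
office-minus-ambulatory difference; a rank-deficient design is an error
that names the offending columns.

Nocturnal dipping is reported descriptively only: nondipping is
night/day systolic ratio > 0.9, the conventional 10%-decline rule, since
the screening comparison never uses it.

## The simulated world

The generator is a stated world, not a tuning knob. Each subject carries a
two-level latent profile: a daytime mean over the device-day window
(06:00–22:00, deliberately distinct from the 10:00–20:00 analysis window)
and a nighttime mean equal to daytime × dip ratio (truncated normal, mean
0.9, SD 0.07 — nondipping is common in the emulated population). Subjects
are drawn as a two-component mixture on the *implied 24-h scale*
`(16·day + 8·night)/24`: exactly `round(n × 0.35)` subjects (the
configured confirmed-hypertension prevalence, permuted across the cohort)
draw implied systolic above 130 mmHg, the rest below 130 with diastolic
below 80. Component membership is assigned by exact count rather than by
Bernoulli draws because the prevalence is a contract of the stated world,
not a quantity to be estimated — and every downstream summary then has a
closed form.

The office offset is a per-subject constant from a mixture: a white-coat
component (weight 0.15, +15 ± 5 mmHg), a masked component (weight 0.40,
−32 ± 8 mmHg), and a zero-centred remainder. The large, strongly negative
masked component is the package's one deliberate calibration: the emulated
study found daytime ambulatory SBP about 7 mmHg *above* office SBP and
sensitivity of 67% at 130/80, which jointly require a dominant
masked-tendency subpopulation. With this preset the simulated cohort lands
sensitivity at 130/80 near 69% (the 60–75% band), screen-positive
fraction near 39%, and a daytime office−ABPM difference near −11 mmHg.
Reading noise is i.i.d. Gaussian within subject (per-subject SD ≈ 9/7
mmHg systolic/diastolic), and all simulated pressures are rounded to
integer mmHg as an oscillometric device reports them.

Missingness is MCAR by design, since count-based quality control is
insensitive to the mechanism: a 10% per-reading dropout plus, with
probability 0.20, a contiguous device-removal window starting between
21:00 and 01:00 and lasting 4–8 h (people take the cuff off to sleep).
The removal mechanism is what generates realistic nighttime QC failures —
about 18% of simulated records fail, matching the excluded fraction in
the emulated study. Covariates (age, sex, three sites, BMI, diabetes,
smoking, medication flag) are drawn independently of the latent pressures;
this keeps the configured prevalence exact cohort-wide, at the price of
not reproducing age–BP or BMI–sensitivity gradients. A green test on this
world therefore establishes pipeline correctness (QC, weighting,
classification, estimation), *not* epidemiological realism of covariate
structure, treatment dynamics, seasonal effects, or smooth circadian
(cosinor) variation within windows.

## Numerical and design choices

* **Flat-profile limit.** "Noise-free implies a perfect test" holds only
  when the profile is flat (dip ratio 1) *and* the screen cutoff matches
  the reference cutoff: with dipping, the office screen measures the
  daytime latent while the reference is the lower 24-h latent, so
  borderline normotensives are structural false positives even without
  noise; and against the fixed 130/80 reference, a confirmed subject with
  a 24-h mean of, say, 136 is a forced false negative at 140/90 no matter
  how clean the measurements. The recovery tests therefore pin dip = 1
  and assert exact perfection at the matched cutoff (all three cutoffs
  classify perfectly only in a "gap" configuration whose latents avoid
  every cutoff band); the dipping noise-free world is instead checked
  against its closed-form 24-h mean to 0.5 mmHg on the integer-rounded
  latents.
* **Parameter recovery.** Under full offset separation, the recoverable
  identities are `1 − specificity → white-coat weight` and
  `1 − sensitivity → masked weight` (the white-coat share *of
  screen-positives* additionally depends on prevalence and is not a
  generator parameter).
* Ties in the empirical AUC count half, via mid-ranks; small instances are
  checked against exhaustive pair enumeration.
* Degenerate inputs are flagged, not coerced: empty analysis windows give
  `NA` means, zero denominators give undefined metrics, constant
  differences collapse the limits of agreement and leave Pitman undefined.
* Medicated subjects (self-report) are excluded from the primary analysis;
  `include_qc_failures` and `exclude_medicated = FALSE` reproduce the two
  sensitivity analyses, reported as side-by-side deltas.
* BMI 30.0 is classed obese (WHO convention); age groups are decade bands.
  Human-readable tables round percentages to integers; the JSON report
  keeps full precision.
* Determinism: the cohort is a pure function of its config (seed
  included); reports are byte-identical across reruns on the same inputs.

## Limitations

Accuracy numbers from the simulator are calibration checks, not estimates
for any real population: the latent model is piecewise-constant with a
single night/day ratio, covariates carry no signal, and the office offset
is time-invariant. The agreement block inherits whatever artefacts the
device produces; only structurally impossible readings are removed by
default. Records longer than ~26 h are truncated at 24 h from fit time
before weighting, which assumes the fit timestamp is trustworthy.
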