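---
title: "Modelling ICU mortality with the nocturnal-diurnal heart rate index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ICU mortality with the nocturnal-diurnal heart rate index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The index

Human heart rate dips at night. The nocturnal-diurnal heart rate index
(NDHRI) quantifies that circadian dip for one ICU day from routinely
recorded 5-minute heart-rate observations: each observation is a bar of
width 5 min and height equal to the heart rate, the night window
(22:00–06:00) and day window (06:00–22:00) each get a cumulative bar area
(bpm·min), and the NDHRI is the ratio of the night area to the day area.
Because the night window is half as long as the day window, a patient with
no circadian variation has an NDHRI of exactly 0.5; a normal nocturnal dip
pushes it below 0.5, and a nocturnal riser pushes it above. If nighttime
heart rate is a fraction $(1-d)$ of daytime heart rate, then

$$\mathrm{NDHRI} \;=\; \frac{480\,\bar h_{\text{night}}}{960\,\bar h_{\text{day}}}
  \;=\; \frac{1-d}{2},$$

with $\bar h$ the duration-weighted window means. The package stores the
index as a fraction (0.432) and renders percentages (43.2%) only in
reports.

In this package a *circadian day* is one daytime window followed by the
night window that begins the same evening, so each daily index describes a
contiguous 24-hour physiological cycle; the pairing across midnight is a
design choice (the alternative — pairing a night with the following day —
is equally defensible, but the same-evening pairing keeps the cycle
contiguous). A stay's exposure is the mean NDHRI over its usable circadian
days, and its *time in range* is the fraction of usable days whose NDHRI
falls inside a closed target interval.

## Missing data and usability

Slots may be missing; missing slots contribute nothing to either area and
are never imputed — imputation would manufacture exactly the circadian
signal being measured. Instead, each window carries a coverage fraction
(present slots / expected slots: 96 at night, 192 by day) and a day is
*usable* only when both windows reach a coverage threshold, 0.80 by
default. The threshold is a construct of this package: the source data
analyses that motivate the index do not state how partially covered days
were handled. Partial admission/discharge windows are handled by the same
rule with no special-casing — a stay admitted at 23:00 simply has an
unusable first circadian day.

## The exclusion cascade

`apply_exclusions()` reproduces a ten-rule eligibility cascade as data: an
ordered ledger of how many stays each rule removed, with each stay
attributed to the *first* rule it violates. Conservation
(`n_input = n_included + sum(excluded)`) holds by construction, and
permuting the rule order can move stays between counts but never changes
who is included — both properties are tested. Choices the rules' prose
leaves open, and how this package resolves them:

* **Rule 1 (no usable consecutive heart-rate record)** is operationalized
  as "no circadian day with ≥ 80% coverage in both windows", computed from
  the recorded vitals span. Coverage is deliberately not clipped to the
  administrative admit/discharge interval, so corrupt admission timestamps
  (a real pathology in multi-center exports) are caught by rule 7 rather
  than masquerading as missing data.
* **Rule 2 (repeat stays)** keeps the earliest admission per patient by
  default (`keep_stay = "last"` is available). A `patient_id` column is
  required for this rule to act; absent one, each stay is its own patient.
* **Rule 7** reads "discharged or deceased within a single calendar day"
  literally: admission and discharge on the same calendar date.
* **Rule 8 (3-SD outliers)** uses per-stay moments computed once on the raw
  series, two-sided `|hr − m| > 3s` with a strict inequality (a point at
  exactly `m + 3s` survives); `side = "upper"` gives the literal one-sided
  reading. Whether the original analysis was per-stay or cohort-wide,
  one- or two-sided, is unstated; per-stay two-sided is the symmetric
  default. Outlier removal deletes *points*, never stays — a stay is
  excluded (under rule 8) only when trimming leaves no usable day. The
  trimming is single-pass by contract: moments are never recomputed on the
  trimmed series.
* **Relaxed mode** (`relaxed = TRUE`) disables rules 1 and 8 only — the
  sensitivity-refit configuration for asking how much the heart-rate
  quality rules drive results.

## The mortality model

The exposure–mortality association is deliberately not forced to be
linear: mortality is modelled as

$$\operatorname{logit} \Pr(Y_{ij}=1) = f(x_{ij}) + \beta^\top z_{ij} + b_j,
  \qquad b_j \sim N(0, \sigma_b^2),$$

where $f$ is a penalized cubic regression spline of the exposure (mean
NDHRI, or time in range), $z$ the linear adjustment set (age, gender, BMI,
APACHE IV), and $b_j$ a Gaussian random intercept for hospital $j$
absorbing between-hospital differences. Fitting, smoothing-parameter
selection (REML) and the Bayesian covariance come from `mgcv`; the random
intercept is the standard smooth-as-random-effect formulation
`s(hospital, bs = "re")`. Defaults: basis dimension `k = 10`, second-order
penalty, logit link.

On the link: odds ratios are the natural contrast under the logit link, so
logit is the default; a log link is available (`link = "log"`) for risk-
ratio-style modelling of a rare outcome, but contrasts are then ratios of
probabilities, not odds.

Everything reported is a functional of the fitted coefficients and their
Bayesian covariance $V_\beta$, with the hospital columns zeroed so all
curves and contrasts are population-level:

* **Curve** — pointwise Wald band on the link scale mapped through the
  inverse link (so bands live in (0, 1)); covariates held at the cohort
  mean (continuous) or mode (categorical). Extrapolation beyond the
  observed exposure range is refused unless forced.
* **Contrast** — $\mathrm{OR}(x_1, x_0) = \exp\{f(x_1) - f(x_0)\}$, delta-
  method SE, Wald p. Antisymmetry $\mathrm{OR}(x_1,x_0) =
  1/\mathrm{OR}(x_0,x_1)$ is exact; no refitting.
* **Nadir** — argmin of the fitted linear predictor over a grid with step
  0.001, with a boundary flag for monotone fits.
* **Smooth significance** — the approximate smooth-term test from
  `summary.gam`, whose null calibration the test suite checks by
  simulation.

The "unadjusted" model variant drops the covariates but *retains* the
hospital random intercept: clustering is a feature of the design, not a
confounder, so it stays in both rows of the contrast table.

## The range rule

The optimal-range derivation is codified (replacing visual inspection of
the smooth curve) as: nadir ± 0.025, endpoints rounded to the nearest
0.005 and clamped to the observed exposure range. A nadir of 0.425 gives
[0.400, 0.450]; a boundary nadir yields an explicit failure status rather
than a range. The time-in-range model then uses exactly the derived range
unless an override is supplied, and any override is recorded in the run
manifest. Its direction is summarized by the average derivative of the
fitted linear predictor over the observed exposure span.

Subgroup analyses refit the full machinery independently per stratum (no
shared smoothing, no pooling, no interaction tests), skipping strata
smaller than `10 * k` rows with a recorded reason. No multiplicity
correction is applied across subgroups; p-values are labelled unadjusted.

## The synthetic cohort generator

Real multi-center ICU vitals are access-controlled, so the package ships a
generator whose ground truth makes every downstream stage testable.

* **Heart rate**: a two-level (square-wave) day/night profile rather than a
  sinusoid, because it makes the true daily NDHRI *analytically exact*:
  $(1-d)/2$ for dip $d$. The test suite exploits this identity to 1e-12.
  Stationary AR(1) noise (marginal SD 5 bpm, lag-5-min correlation 0.7) is
  added per slot, values are clipped to the physiologic guard range 20–250
  bpm, and slots are dropped independently at the missingness rate (0.1).
* **Stay-level dips** are Gaussian (mean 0.136, SD 0.112, clamped to
  (−0.45, 0.95), so nocturnal risers exist), chosen so the true NDHRI is
  approximately 43% ± 6% — the observed distribution in large mixed ICU
  cohorts. Day-to-day dip variation within a stay (SD 0.02, i.e. a daily
  NDHRI SD of one percentage point) makes time-in-range vary continuously
  across stays.
* **Covariates** (age 62.6 ± 16.4 y, 54.9% male, BMI 29.3 ± 7.9, APACHE IV
  log-normal with median 54 and IQR ≈ [40, 71], ethnicity/ICU-type/
  comorbidity frequencies) mirror the same cohort class. Stay lengths are
  log-normal with median 4 days. Admissions are spread over a year with
  uniform clock times, so window segmentation is exercised at every phase.
* **Mortality**: logit risk = logit(0.117) + $c\,(x^\ast - \nu)^2$ +
  centered covariate terms + hospital intercept (SD 0.3 across 20
  hospitals), with $x^\ast$ the stay's true NDHRI, nadir $\nu = 0.425$ and
  curvature $c = 3000$ log-odds per squared fraction. The curvature is
  anchored to the steepest published contrast for this index
  ($\log(6.73)/0.025^2 \approx 3000$). A consequence worth stating
  plainly: a *globally* quadratic logit with that local curvature implies a
  marginal cohort mortality far above the ~12% seen in real cohorts,
  because the quadratic keeps climbing in the tails where a real risk
  curve flattens. The generator accepts this distortion — the baseline
  0.117 is the nadir-level anchor, and with zero curvature (the null
  configuration) the cohort mortality calibrates to 11.7% exactly, which
  the tests check. ICU death is drawn as a sub-event of hospital death
  (conditional probability 0.538).
* **Time-in-range truth**: with day-to-day dip SD $s$, the true proportion
  of days in range $[l, u]$ is $\Phi((u-\mu)/(s/2)) - \Phi((l-\mu)/(s/2))$
  for a stay with true index $\mu$; `tir_effect` ties log-odds linearly to
  that proportion for experiments where time in range, not the U, is the
  causal channel.
* **Planted violations**: `inject_exclusion_cases()` mutates a configured
  fraction of stays to violate exactly one exclusion rule each and emits a
  manifest, so the cascade's attribution can be checked stay by stay. The
  rule-8 mutation is sized so that 3-SD trimming pushes every night window
  of the stay just below the coverage threshold; the rule-7 mutation
  corrupts admission metadata while leaving vitals intact.

What the generator does *not* emulate: realistic hemodynamic waveforms,
sleep architecture, sedation or beta-blockade as dynamic processes,
informative (non-random) missingness, or the flattening tails of the real
risk curve. Passing recovery tests therefore demonstrates that the
pipeline estimates what it claims to estimate under a known circadian
signal — not that the clinical effect sizes transfer to any real cohort.

## Numerical choices

* Timestamps are snapped to the nearest 5-min grid slot; duplicate
  (stay, slot) rows collapse to their mean with a warning.
* Clock arithmetic is integer minutes since epoch, UTC; a circadian day is
  indexed by `floor((t - 06:00) / 24h)`.
* Window areas are plain sums of `5 * hr` — no trapezoids, matching the
  bar construction of the index.
* Range membership uses a closed interval, so an NDHRI of exactly 0.400
  counts as in-range.
* The nadir grid step (0.001 in exposure fraction) contributes at most
  half a step of quantization error, negligible against the statistical
  error of the smooth.
* Degenerate inputs fail softly where the science says they should: a day
  with zero daytime area is unusable (no division), a stay with no usable
  day gets a flagged summary rather than an exception, a constant
  time-in-range exposure yields a flat-model warning, a single-hospital
  cohort downgrades the random intercept with a warning.

## Problem sizes in the test suite

The simulation studies in the tests use the scales at which their
conclusions are stable: closed-form and oracle checks on hundreds to a
thousand random series; nadir/odds-ratio recovery on 20 replicates of
5,000-stay cohorts; null calibration of the smooth test on 200 replicates
of 1,000 stays; time-in-range direction on a single 10,000-stay cohort.
With the frozen defaults the nadir estimator's replicate SD at n = 5,000
is about 0.002, so the ±0.01 recovery band is comfortable while the
rounded-range reproduction (which needs the nadir within ±0.0025) is
expected to succeed in roughly 80–90% of replicates — the recovery
experiment reports both.

## Known limitations

* The U-shaped truth is globally quadratic; real risk curves flatten in
  the tails, so tail odds ratios from the generator are not clinically
  calibrated.
* The smooth-term p-value is the usual approximate GAM test; its finite-
  sample calibration is verified by simulation only at the null
  configuration shipped in the tests.
* The exclusion cascade's rule 1 and rule 8 depend on the coverage
  threshold, which has no empirical anchor; sensitivity to it is exposed
  through configuration, not resolved.
* `read_tables()` expects the package's CSV schemas (a documented column
  mapping, not the raw relational schema of any particular ICU database),
  and does no database connectivity.
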