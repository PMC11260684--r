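# ndhri

Circadian heart-rate analysis for ICU cohorts: the **nocturnal–diurnal
heart rate index (NDHRI)** and its association with mortality.

Human heart rate normally dips at night. For one ICU day, the NDHRI
compresses that circadian pattern into a single ratio built from routine
5-minute heart-rate observations: treat every observation as a bar of
width 5 min and height equal to the heart rate, sum the bar areas over the
night window (22:00–06:00) and over the day window (06:00–22:00), and take

```
NDHRI = night area / day area
```

Because the night window is half the length of the day window, a patient
with no circadian variation scores exactly 0.5; if nighttime heart rate is
a fraction (1 − d) of daytime heart rate, the NDHRI is (1 − d)/2. A
stay-level exposure is the mean NDHRI over the stay's usable circadian
days, and the mortality association is modelled as a penalized-spline
logistic GAM

```
logit P(death) = f(mean NDHRI) + β' (age, gender, BMI, APACHE IV) + b_hospital
```

with a Gaussian random intercept per hospital (fit via mgcv, REML). From
the fitted smooth the package extracts the risk curve with its 95% band,
Wald odds-ratio contrasts between exposure values, the nadir of the
U-shaped curve, a codified "optimal range" rule (nadir ± 2.5 points,
rounded to 0.5 points), and a time-in-range model relating the proportion
of days spent inside that range to mortality.

The package is aimed at researchers working with eICU-style exports
(5-minute vitals plus stay-level covariates) and at methodologists who
want a fully testable twin of such an analysis: a synthetic cohort
generator with known circadian and mortality ground truth makes every
stage — the ten-rule exclusion cascade with its attrition ledger, the
index computation, the GAM, the range rule — checkable by parameter
recovery, without access-controlled data.

## Worked example

```r
library(ndhri)

cfg <- ndhri_sim_config(n_stays = 5000)   # synthetic eICU-style cohort
report <- run_study(cfg, seed = 1)        # simulate -> exclude -> NDHRI -> fit
print(report$nadir$nadir)                 # 0.4228773
print(report$range)
# Optimal NDHRI range: [0.400, 0.450] (nadir 0.423 +/- 0.025, rounded to 0.005)
print(report$contrasts$adjusted)
# OR(0.398 vs 0.423) = 4.00 (3.09-5.18), Wald p = 5.11e-26
# OR(0.448 vs 0.423) = 3.72 (2.88-4.82), Wald p = 1.31e-23
print(report$tir)
# Time-in-range model (range [0.400, 0.450]):
#   average derivative of the linear predictor: -3.63 (declining trend), smooth p = 0
```

Reading the output: the fitted mortality curve over mean NDHRI is
U-shaped with its minimum near 0.423 (the generator's true nadir is
0.425), the codified range rule recovers [0.400, 0.450], mortality odds
are 3–4 times higher 2.5 points away from the nadir on either side, and
stays spending more days inside the range have lower mortality (negative
average derivative of the fitted linear predictor, p < 0.001).

The same machinery runs on real tables:

```r
tb <- read_tables("vitals.csv", "stays.csv")
ex <- apply_exclusions(tb$stays, tb$vitals)   # ten-rule cascade + ledger
print(ex$ledger)
su <- summarize_stays(ex$daily)               # mean NDHRI, time in range
fit <- ndhri_gam(merge(ex$stays, su[su$usable, ], by = "stay_id"))
summary(fit); plot(fit)
```

A thin CLI over the same functions lives at `inst/cli/ndhri-cli.R`
(subcommands `simulate`, `cohort`, `ndhri`, `fit`, `report`, `recover`).

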