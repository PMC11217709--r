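---
title: "Methods: biomarker derivation, the multilevel model, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomarker derivation, the multilevel model, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`wearlab` turns minute-level wearable streams from older adults into
daily sleep, heart-rate-variability (HRV) and physical-activity
biomarkers, and asks whether within-person deviations in those
biomarkers predict daily depressive-symptom reports. This vignette
documents the procedures, the assumptions behind the synthetic cohort,
and the numerical choices, in enough detail that a reader can audit or
re-derive any of them.

## 1. Nightly sleep scoring

Each night is scored inside an 18-hour window from 6 PM to noon the
following day, wide enough to contain any plausible sleep period for
this population. One participant per cohort may be a day/night-reversed
sleeper; their window runs 6 AM to midnight of the following day so
that each window still closes before the morning report it feeds.

The device's minute-level asleep/awake classification is first passed
through the standard actigraphy rescoring criteria, in order, each rule
reading the output of the previous one:

1. If the 4 minutes before the start of a sleep period were awake, the
   first minute of the sleep period is set to *sleep*. The default
   (`rule1_direction = "as_printed"`) keeps this direction even though
   it is a no-op; the classic rescoring literature rescores that minute
   to *awake*, available as `"webster"`. Both directions are exposed
   and tested because the sources for this rule family disagree, and
   neither direction changes any downstream metric by more than one
   minute per sleep period.
2. After 10 or more awake minutes, the first up-to-3 minutes of the
   following sleep period become awake. The rule is applied in a single
   pass against a snapshot of the series: awake runs lengthened by the
   rule itself do not re-trigger it within the pass. A consequence,
   verified by test, is that the full rescoring pipeline is *not*
   idempotent (a second pass can trim further minutes after a rule-2
   extension); the isolated-bout stages below are idempotent on their
   own.
3./4. A sleep period shorter than 6 minutes with more than 15 awake
   minutes immediately before *and* after is rescored to awake. The
   sentence structure of the rule reads most naturally as one two-sided
   rule, and that is how it is implemented; a sleep bout at the edge of
   the window has no flank on one side and is never removed.
5. Likewise for sleep shorter than 10 minutes flanked by more than 20
   awake minutes.

Missing minutes break runs everywhere: they are neither asleep nor
awake, never relabelled, and a rule window or a "consecutive sleep"
run cannot span one. Sleep onset is the start of the first run of at
least 10 uninterrupted asleep minutes, offset the end of the last such
run; a night without one is invalid rather than an error.

Metrics over the inclusive onset–offset span: time in bed (inclusive
minute count), total sleep time (TST, asleep minutes), awakenings
(awake runs of **2 or more** minutes — the strict reading of awake "for
more than 1 minute"), the sleep fragmentation index SFI = awakenings
per minute of TST, sleep efficiency SE = 100·TST/TIB, and long
fragmentation episodes. The long-episode threshold is not defined by
the sources naming the metric; the package defaults to awake runs ≥ 5
minutes, configurable. Nights with more than 20% missing minutes inside
the span are flagged invalid — a conservative validity rule chosen
here, since the sources are silent.

Every rescoring path is verified against an independent literal-scan
oracle: exhaustively for all binary sequences up to length 14 (where
only rules 1–2 can fire — rules 3/4 need at least 33 minutes and rule 5
at least 43), and by seeded random batteries over longer sequences with
and without missing minutes so the isolated-bout rules are exercised
too.

## 2. HRV

Minute heart rate cannot carry beat-to-beat variability. `hr_to_rr()`
reconstructs an R-R series by contributing `round(h)` intervals of
`60000/h` ms per minute — an explicit approximation, flagged in output
metadata, whose within-window variability comes only from
minute-to-minute heart-rate changes. Spectral behaviour is therefore
validated on synthetic beat-level series (`synth_rr_series()`), which
carry genuine beat-scale modulation.

Filtering removes intervals outside 300–2000 ms, then intervals more
than 20% away from an 11-point running median. Windows are 5 minutes,
clock-aligned, non-overlapping, computed around the clock; a window
needs at least 30 intervals to be valid. SDNN uses the population SD
(divide by *n*; documented and tested), RMSSD the root mean square of
successive differences. Spectral powers come from an FFT periodogram of
the 4 Hz cubic-spline-resampled, mean-removed interval series,
integrated over the standard band edges VLF 0.0033–0.04 Hz, LF
0.04–0.15 Hz, HF 0.15–0.40 Hz (the named sources give bands but not
edges; the conventional task-force edges are used). The one-sided
normalization makes the total across all bins equal the variance of the
resampled series, so band sums can never exceed total power (tested).
The ratio is stored as LF/HF. Daily summaries are unweighted means over
valid windows; a day with no valid window is missing for HRV.

## 3. Activity and feedback

Daily activity indicators are direct aggregates: step total, minutes
per device-assigned intensity class (consumed as given, never
recomputed from accelerometry), and the longest inactive run — minutes
with zero/missing steps and sedentary/missing intensity. Missing
minutes count as inactive by default (a device that is off could itself
signal an emergency); this is configurable.

Traffic-light feedback compares each day against the participant's
first calendar week: per domain (stress = daily mean HF power, sleep =
nightly SFI, steps, activity = light+moderate+intense minutes) the
baseline is the week-1 mean and sample SD (n−1), requiring at least 2
non-missing days. Green is a value above mean+1 SD, red below mean−1
SD, yellow inside the band with the boundaries inclusive to yellow
("within ±1 SD" belongs to yellow), and gray for a missing value or
invalid baseline. For the sleep domain green and red are swapped, since
higher fragmentation is worse. With a degenerate zero-SD baseline the
bands collapse but still tile the line (any deviation is green/red);
the baseline row carries the SD so consumers can flag this. The
baseline is fixed after week 1, not rolling, matching a first-week
anchor design. Whether "green" for higher HF is clinically *good* is
left as the design's own convention; the rule is implemented as
specified.

Emergency alerts are evaluated per day with strict thresholds: heart
rate below 30 bpm, above 140 bpm (140 exactly does not trigger), and an
inactive run exceeding 480 minutes (exactly 8 h does not trigger), one
alert per trigger per day at the first crossing.

## 4. The day-level model

Each analysis day carries the sleep metrics of the night *ending that
morning* (the window that starts the previous evening), the day's HRV
and activity summaries, the same-day symptom binary, and the next
calendar day's binary. The first 7 calendar days per participant (the
adaptation week) are excluded by default. The "same-day" sleep
convention — night before the report, not after — follows the direction
the design itself emphasizes (the previous night predicting the day),
and the generator offers a `couple_to` switch for the strictly
concurrent alternative.

Daily predictors are person-mean centered over each participant's
retained days, so the coefficient isolates within-person deviation from
one's own average; level-2 covariates (age, sex, chronic conditions,
baseline depression) are grand-mean centered. The fragmentation index
enters the model as SFI×100 — awakenings per 100 minutes of sleep — so
that a unit change is a meaningful within-person contrast (raw SFI has
a within-person SD of ~0.01; a per-raw-unit odds ratio would be
uninterpretable). Sleep efficiency enters in percent.

Each model is a random-intercept logistic regression fitted by maximum
likelihood with adaptive Gauss–Hermite quadrature (10 points; Laplace
fallback on failure), one daily predictor at a time plus the four
covariates, available-case per model (with a single level-1 predictor
per model this is the operative equivalent of full-information
handling; no imputation). Wald intervals are formed on the log-odds
scale and exponentiated. Degenerate predictors (no within-person
variance) and possible separation (|β| > 15 or SE > 10) are reported as
errors/non-convergence, never silent estimates. The battery is 11
predictors × 2 outcomes; Holm's step-down correction is applied within
each outcome family of 11 at family α = .05 (via `p.adjust`, with the
step-down logic verified by hand in tests), alongside the fixed
p < .005 threshold flag.

Pre/post comparisons use a hand-implemented exact Wilcoxon signed-rank
test — zero differences dropped (the classical convention), midranks
for ties, exact two-sided p from the signed-rank distribution built by
shift convolution over doubled ranks for n ≤ 25, normal approximation
with tie correction beyond — because the stock implementation cannot
produce exact p-values under ties. It is cross-checked against
`wilcox.test` in tie-free cases and against full 2^n enumeration for
n ≤ 8. Usability uses a paired t-test, and its age moderation a 2×2
mixed ANOVA (time within; over-75 vs 65–74 between, with 76 in the
older group). Group descriptives use Welch t, chi-square, or Fisher's
exact test per variable type.

## 5. The synthetic cohort

The emulated study deposited no participant data, so the generator is a
first-class, tested module whose defaults *are* the study conditions:
25 participants, 33 days (or any 8–40-day profile), symptom-day
prevalence 0.37, per-domain day-level missingness of 23% (survey),
33.3% (HRV), 54.5% (sleep), 36.9% (steps), demographics matched to the
published cohort table, one reversed-cycle sleeper, one participant
missing the post-test, and true within-person couplings defaulting to
the published same-day odds ratios (2.066 per SFI×100 unit, 0.972 per
SE percentage point).

Everything distributional beyond those anchors is an artifact choice,
made once and documented here:

- **Nights.** Person-level targets: TST ~ N(320, 80) min, SE ~
  N(66, 10)%, bedtime ~ 22:45 ± 30 min across persons (±25 min across
  nights), rise capped at 07:30. Nightly wake volume is
  (1 − SE_target/100) of time in bed with log-normal night-to-night
  jitter (σ = 0.30); wake episodes have person-specific mean duration
  ~ logN(log 18, 0.3) minutes, geometric lengths (episodes of exactly
  1 minute do not count as awakenings), uniform placement inside the
  in-bed span, and no uninterrupted sleep run longer than 400 minutes
  (rare in this age group, and it guarantees an awake minute inside any
  long overnight span for the activity scheduler). Scored against the
  package's own sleep module, a default cohort lands near TST 320,
  SFI 0.02 and SE in the high 60s–70s with the published spread.
- **Symptom coupling.** A day's symptom probability is
  logit⁻¹(α_i + β_sfi·SFIc + β_se·SEc) using the previous night's
  *scored* metrics centered on the person's mean over their own
  generated nights. Centering on a person-constant mean (rather than a
  running mean) is deliberate: any person-constant offset between
  generator-side and analysis-side centering is absorbed by the model's
  random intercept, which makes the within-person coefficient exactly
  recoverable — the property the Monte-Carlo acceptance checks verify.
  A running-mean centering would instead attenuate the fitted log-odds
  by roughly (1 − H_D/D) ≈ 10% at D = 33 (H_D the harmonic number),
  which is measurement-error attenuation, not a property of the
  analysis.
- **Person intercepts.** α_i = a₀ + 0.6·z(GDS) − 0.06·(SE_target_i −
  66) + 0.9·Z. The GDS and habitual-efficiency terms create the
  expected between-person correlations (baseline depression positively,
  habitual sleep efficiency negatively, anchored to the published
  person-level correlation of about −0.47); both are person-constant
  and therefore do not bias the within-person slopes. a₀ is calibrated
  to the 0.37 prevalence with the standard logit-normal marginalization
  a₀ = logit(0.37)·√(1 + 0.346·v), v the nominal linear-predictor
  variance.
- **Heart rate.** Person base ~ N(72, 4) bpm, circadian cosine
  (amplitude 5, acrophase 15:00, shifted 12 h for the reversed
  sleeper), −7 bpm while asleep, +steps/10, AR(1) noise (σ = 2,
  ρ = 0.7), clamped to 40–120 bpm. The clamp keeps default cohorts free
  of heart-rate emergencies (a negative-control property under test);
  widen it to inject pathology.
- **Activity.** Five daily bouts anchored through the waking day (the
  first within ~25 minutes of rising), per-person volume multiplier
  logN(σ = 0.6) around 130/14/22 light/moderate/intense minutes,
  steps per minute by class, sporadic low-step "puttering" minutes, and
  a scheduler guard that stirs an awake minute inside any ≥ 460-minute
  zero-step span (a nocturnal bathroom trip) so that worn days never
  cross the 480-minute alert threshold.
- **Missingness.** Missing-completely-at-random at the participant-day
  level, independent per domain, because only the marginal day counts
  are published and MCAR is the weakest mechanism consistent with them.
  Exactly `round(rate·N)` units are masked per domain, so printed
  fractions like 440/808 are reproduced exactly at the published
  denominators and realized rates converge to the targets in any large
  cohort. Sleep missingness masks whole nights (the night carries the
  following day's sleep measures).

What the generator does **not** emulate — and hence what passing tests
do not show about real data: device-specific sleep/step classification
error, beat-level HRV in the minute stream (minute-level SDNN values
are an order of magnitude below wrist-device summaries; only the
synthetic beat-level series have realistic spectra), informative
(non-MCAR) missingness such as symptomatic participants wearing the
device less, autocorrelated symptom runs beyond what sleep coupling
induces, and seasonal or weekday structure.

## 6. Monte-Carlo design and problem sizes

The recovery studies (`recovery_study()`, `scripts/acceptance.R`)
simulate 200 cohorts of 25×33 days per target at day-level generation,
activate only the target coupling (the other sleep coefficient set to
zero, the standard single-parameter recovery design), apply the study
missingness, and fit the same-day model for the target predictor.
Because the estimand is the log odds ratio, replicate estimates are
averaged on the log scale and exponentiated; the arithmetic mean of the
ORs is also reported (it carries the usual Jensen inflation of
exp(·)). Around 2–3% of replicates end with optimizer warnings and are
excluded as non-converged. The null type-I-error check runs 200
replicates of 15×25 cohorts with both couplings at zero and counts
fixed-threshold (p < .005) rejections. These replicate counts and
cohort sizes are the package's chosen balance between Monte-Carlo error
(SE of the mean log-OR ≈ 0.02 at 200 replicates) and a test suite that
runs in minutes.

All randomness flows from a single integer seed: the generator seeds
the RNG at entry, every downstream draw continues that stream, and
identical configuration + seed yields byte-identical written cohorts
and pipeline manifests (tested via file hashes).

## 7. Known limitations

- The minute-level R-R reconstruction is a stated approximation; no
  claim is made that its SDNN/HF values match beat-level magnitudes.
- The rescoring rule set is implemented as printed, including the
  no-op direction of criterion 1 by default; users wanting the
  classical behaviour must opt into `"webster"`.
- Available-case fitting is the operative missing-data strategy; with
  informative missingness the estimates would inherit its bias.
- The exact Wilcoxon p-value uses the signed-rank distribution
  conditional on the observed (mid)ranks, the standard exact treatment
  under ties; other tie conventions exist.
- The generator's between-person pathways are minimal (baseline
  depression and habitual sleep efficiency only); person-level
  correlations among HRV/activity markers arise only incidentally.
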