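---
title: "Measuring brace wear from an embedded temperature sensor: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring brace wear from an embedded temperature sensor: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bracewear)
```

## What this package models

A slim-fit knee brace carries a small temperature logger sampling once every
`sampling_interval` minutes (default 10) with a precision of ±0.1 °C. While
the brace is worn, the sensed temperature relaxes toward skin-contact
temperature; off the body it relaxes back toward ambient. Wear time is the
quantity of clinical interest — participants are typically advised to wear
the brace at least an hour a day — and the package compares two ways of
measuring it: the objective sensor signal and a daily self-report log.

Three models sit at the core:

1. a **generative model** of cohorts (wear schedules, sensor physics,
   self-report behaviour) with complete ground truth;
2. a **detection model** that converts a temperature series into wear bouts;
3. an **agreement model** (CCC + Bland–Altman LoA with repeated-measures
   handling) that quantifies how well self-report tracks the sensor at six
   aggregation levels.

## The synthetic cohort generator

### Wear behaviour

Each participant-day is a Bernoulli draw with probability `p_wear_day`
(default 0.7) of containing one wear bout; bout durations are normal
(`bout_minutes_mean` 70, `bout_minutes_sd` 30 min) truncated below at the
sampling interval and rounded to whole minutes; start times are uniform
between 08:00 and 21:00 and bouts are truncated at 23:59 unless
`allow_midnight_span` is set. The 70-minute mean reflects an
at-least-an-hour-a-day prescription; start times and the one-bout-per-day
simplification are plausibility choices, not observed facts — real bout-length
and time-of-day distributions for knee braces are unreported.

Real adherence cohorts are strongly heterogeneous, and the aggregated
agreement measures are only meaningful when participants differ. Two
between-participant random effects provide this: a log-normal multiplier on
the bout mean (`subject_bout_sdlog`, default 0.35 — participant means
roughly 40–120 min/day) and a logit-normal shift on the wear-day
probability (`subject_pwear_sdlogit`, default 0.8 — wear-day rates roughly
0.45–0.90). Both act on transformed scales so degenerate configurations
(`p_wear_day` of 0 or 1) remain exact; setting both SDs to 0 recovers a
homogeneous cohort.

### Sensor physics

Temperature follows first-order (Newtonian) relaxation integrated at the
sampling interval: toward `t_skin` (32 °C) with time constant `tau_on`
(15 min) while worn, toward ambient with `tau_off` (20 min) otherwise.
Ambient is a sinusoid (`t_ambient_mean` 22 °C, amplitude 2 °C, peak at
15:00). Transient ambient steps (`confounder_amp` 8 °C for
`confounder_duration` 40 min at `confounder_rate` 0.1/day) emulate hot cars
and air-conditioned rooms; by default they occur only off-wear, because a
hot car during wear is physically confounded with wear and would make
ground truth ambiguous. Gaussian sensor noise (SD 0.2 °C) is added and the
result quantized to 0.1 °C (half away from zero, normalized to its decimal
representation so CSV round trips are bit-exact).

The wear mask uses the half-open convention — a sample at time *t* is worn
iff `don ≤ t < doff` — which avoids double counting at transitions, and the
relaxation target over `(t_k, t_k+1]` is the state at `t_k`. A sample-aligned
70-minute bout therefore covers exactly 7 samples, and the first warming
step equals `(t_skin − T)(1 − e^(−Δt/tau_on))` ≈ 4.9 °C for the default
physics.

### Self-report behaviour

For a true wear day the reported value is
`round_to(rounding, max(0, gain × true + Normal(0, noise_sd)))` with
`gain` 1, `noise_sd` 20 min and `rounding` 15 min (round half away from
zero — deterministic, and how people actually round). A true no-wear day is
reported as worn with probability `p_phantom_day` (0.15), with minutes drawn
from the bout distribution. Each day's entry is missing entirely with a
small probability: 0.005 at baseline, but 0.31 for one designated
participant — mirroring cohorts in which one person accounts for almost all
missing logs (about 13 of 15 missing entries in a 10 × 42 cohort). This
model can produce both signatures seen when self-report meets an objective
sensor: under-reporting of average minutes and over-reporting of days worn.

One consequence worth knowing: with 20-minute recall noise, short true
bouts (10–40 min) are reported as zero 15–45% of the time, which *removes*
self-reported wear days at nearly the rate phantom days add them. The
days-worn bias direction is therefore close to neutral under these
defaults; it becomes reliably positive only when recall noise is small or
phantom reporting is stronger.

### What the generator does not emulate

Skin-temperature physiology beyond first-order relaxation (sweating, local
perfusion), brace repositioning, battery or storage effects, device
failures, and any correlation between wear behaviour and reporting
behaviour (e.g. low adherers over-reporting more). Tests passing on this
generator show the pipeline's arithmetic and its statistical machinery are
sound under controlled conditions; they do not validate the detector
against real knee-brace data.

## The detector

Detection operates on first differences, so it is invariant to constant
ambient shifts; the diurnal cycle moves at most ~0.09 °C per sample, far
below threshold. A donning event fires at the first sample of a run of at
most `confirm_samples` (2) consecutive positive differences whose sum
reaches `theta_on` (1.5 °C); doffing analogously. The noise-free donning
step (~4.9 °C) clears the default threshold more than threefold, while a
quantized noise difference (SD ≈ 0.28 °C) crosses it with probability
~10⁻⁷ — the thresholds are design decisions, config-exposed, not literature
values.

Pairing is an alternating state machine: DON opens, next DOFF closes;
repeated DONs while worn are ignored; a DOFF as the very first event closes
a bout assumed open at the record start, and a bout open at the record end
closes at the last sample. Bouts shorter than `min_bout` (10 min) are
dropped, then bouts separated by at most `merge_gap` (10 min) merged.
Records are split wherever a sampling gap exceeds twice the sampling
interval, so logger outages cannot create spurious gradients. Event
instants sit at the first sample of the triggering run, giving a documented
±1-sample transition uncertainty (bout edges land at most one sample away
from truth, partially cancelling in durations).

The optional plateau check (`plateau_check`) cancels a donning event unless
temperature holds ≥ `plateau_delta` (3 °C) above the pre-don level for
≥ `plateau_samples` (2) consecutive samples in a short look-ahead window; a
cancelled transient also takes its own falling edge with it, so a brief
spike cannot leave an orphaned DOFF behind. The check rejects one-sample
transients but **cannot** reject sustained ambient steps of near-skin
magnitude: an 8 °C step with a 20-min cooling constant stays more than 3 °C
above baseline for several samples and is indistinguishable from wear by
this rule. That is a genuine physical limitation of gradient detection with
a single thermistor, flagged rather than hidden.

## Aggregation rules

Days run midnight to midnight in naive local time (single-site use;
timestamps carry no timezone semantics and a `tz` column in input files is
ignored with a warning). Interval minutes are attributed to days by exact
overlap, so cross-midnight bouts split and totals are conserved to the
minute. A sensor day with no detected wear is an observed zero — never
missing; a self-report day is missing only when no log row exists. Rolling
averages are trailing, labelled by the window's last day, and require the
full window to be calendar-contiguous and observed; edge behaviour is
otherwise undefined in the field, and complete-window trailing means are
the transparent choice. Summaries divide by each source's own observed
days (a flag-free default; restricting the sensor denominator to jointly
observed days is possible by aligning the inputs first).

## Agreement estimation

The default CCC is Lin's moment estimator with divisor-*n* variances,
pooled over all pairs at every level. For the repeated levels a
variance-components alternative (`estimator = "vc"`) fits a subject
random intercept plus a shared subject-day effect with a fixed method
shift, and reports concordant variance over concordant-plus-discordant
variance plus the squared shift — useful when pooling is suspect, but the
pooled estimator is the transparent default and its CI is made
repeated-measures-aware instead.

Differences are `selfreport − sensor` everywhere, so over-reporting is a
positive bias; the orientation travels in the output metadata. LoA use the
naive pooled SD of all differences by default, with the
multiple-observations-per-individual ANOVA correction behind
`loa_rm_correction` (the between-subject variance component is rebuilt from
mean squares with the unbalanced-design effective replication).

CIs: cluster bootstrap (participants resampled with replacement, rows kept
intact, percentile interval, default 2000 resamples, seeded) for daily and
rolling panels; Fisher z-transform with n = participants for aggregated
levels, degenerating to a point interval with a warning at |CCC| = 1.
Percentile intervals with ~10 clusters run a few points below nominal
coverage — a known small-cluster property worth remembering when reading
the daily-level CIs for small cohorts.

Band boundaries are inclusive at 0.5 and 0.75 ("moderate") and at 0.9
("strong"): the conventional banding notation assigns both edges of
0.5–0.75 to moderate, and the 0.75 conflict is resolved in favour of the
lower band's upper edge.

## Sensitivity analyses

Impute-as-no-wear turns every missing self-report day into an observed
zero — self-report only, since sensor zeros are measurements. The exclusion
scenario drops the participant with the most missing log days (ties broken
by id order, so the choice is reproducible), erroring if fewer than two
would remain. With no missing data both scenarios reduce to the primary
analysis exactly. Imputation can only add pairs; exclusion can only remove
them.

## Numerical and degenerate-input choices

* Rounding is half-away-from-zero throughout (sensor quantization,
  self-report); R's banker's rounding is never used for these.
* Truncated-normal draws use inverse-CDF sampling and degenerate cleanly
  at SD 0.
* RNG: every participant draws from named substreams derived from the
  master seed, so cohorts are bit-reproducible and earlier participants
  are unchanged when the cohort grows.
* `lin_ccc` refuses two constant vectors (undefined), `ccc_band` refuses
  values outside [−1, 1], summaries refuse all-missing participants, and
  readers reject duplicate timestamps/dates, non-monotone times, negative
  minutes and minutes above 1440 with line numbers.

## Problem sizes used in the simulation studies

The packaged checks run at the study scale — 6-week windows at 10-minute
sampling: a 50 × 42 noise-free cohort and 100 noisy 1 × 42 seeds for
detection recovery; 10 × 42 cohorts across 50 seeds for the directional
self-report bias checks; 200 replications of a 10 × 42 grid for the
rolling-window variance law; 300 simulated cohorts × 500 resamples for the
cluster-bootstrap coverage study; 10⁴ draws for LoA calibration. These
sizes give Monte-Carlo error well inside the margins being tested.

## Known limitations

Single-thermistor gradient detection cannot separate sustained near-skin
ambient events from wear; the generator's behavioural defaults are
plausibility choices where the field reports none; the variance-components
CCC assumes normal random effects; and percentile cluster-bootstrap CIs
undercover somewhat with very few participants.
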