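# bracewear

Objective measurement of knee-brace wear time from an embedded temperature
sensor, and quantification of how well daily self-report agrees with it.

## The problem

Adherence to orthosis interventions ("wear time") is usually measured with
daily self-report logs, which are prone to recall and social-desirability
bias and to missing entries. A small temperature sensor embedded in the
brace offers an objective alternative: skin contact drives the sensed
temperature toward skin temperature with a short time constant, and removal
lets it relax back to ambient, so donning and doffing appear as sharp
temperature spikes and drops. This package is for rehabilitation and
adherence researchers who want to (a) turn raw temperature logs into wear
bouts and daily wear minutes, (b) compare the result with self-report at
several aggregation levels, and (c) test how robust that comparison is to
missing log entries — plus a fully ground-truthed synthetic cohort generator
so every stage is testable without participant data.

## Methods at the core

- **Wear detection** works on first differences of the temperature series
  (gradient-based, hence insensitive to ambient level): a donning event is
  declared when a run of at most `confirm_samples` consecutive positive
  differences accumulates to `theta_on` (default 1.5 °C per 10-min sample),
  doffing analogously for drops; an alternating state machine pairs events
  into bouts, drops bouts shorter than `min_bout` and merges bouts separated
  by at most `merge_gap`.
- **Aggregation** attributes bout minutes to calendar days by overlap with
  local midnight-to-midnight windows and produces the five outcome
  measures: daily minutes, 3- and 7-day trailing rolling averages (complete
  windows only), cumulative total, average daily wear, and days worn.
- **Agreement** uses Lin's concordance correlation coefficient,
  `CCC = 2 s_xy / (s_x² + s_y² + (x̄ − ȳ)²)`,
  and Bland–Altman 95% limits of agreement, `bias ± 1.96 SD(d)` with
  `d = selfreport − sensor`. Confidence intervals respect the
  repeated-measures structure: a cluster bootstrap over participants for
  daily/rolling panels, a Fisher z-transform interval (n = participants)
  for the aggregated ones. CCC bands: < 0.5 poor, 0.5–0.75 moderate,
  0.75–0.9 strong, > 0.9 excellent.
- **Sensitivity analyses**: missing self-report imputed as no-wear days,
  and exclusion of the participant holding most of the missingness.

## Worked example

```r
library(bracewear)

cfg <- sim_config(n_participants = 4, n_days = 14, seed = 7)
cohort <- simulate_cohort(cfg)                      # sensor + logs + truth
wend <- cfg$start_date + 13
sensor_daily <- detect_daily_minutes(cohort$sensor, cfg$start_date, wend)
selfrep <- selfreport_daily(cohort$selfreport, cfg$start_date, wend)
tab <- agreement_table(sensor_daily, selfrep,
                       levels = c("daily", "avg_daily", "days_worn"),
                       n_boot = 500, seed = 7)
```

```
     level n_pairs   ccc ccc_lo ccc_hi   bias loa_lo loa_hi   band
     daily      50 0.809  0.722  0.892  5.700  -46.6   58.0 strong
 avg_daily       4 0.804 -0.270  0.986  0.607  -20.1   21.4 strong
 days_worn       4 0.481 -0.697  0.957 -1.000   -7.2    5.2   poor
```

Reading this: across 50 participant-days the detected and self-reported
minutes agree strongly (CCC 0.81), but a single day's self-report can be
off by roughly −47 to +58 minutes (the LoA); averaging over the whole
window keeps the agreement but shrinks the disagreement band to about
±20 min/day; counting days worn agrees worst — with only 4 participants the
interval is wide. Larger cohorts (the `analysis/` scripts use 10 × 42) show
the characteristic pattern: agreement improves monotonically from daily to
rolling to aggregated outcomes while LoA narrow roughly with the square
root of the averaging window.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on a simulated
cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R   --seed 1   # cohort + ground truth
Rscript analysis/02_detect.R               # bouts + recovery vs truth
Rscript analysis/03_aggregate.R            # daily series + summaries
Rscript analysis/04_agreement.R  --seed 1  # six-level CCC/LoA + figures
Rscript analysis/05_sensitivity.R --seed 1 # missing-data scenarios
```

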