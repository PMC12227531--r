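# dmobench

Digital mobility outcomes (DMOs) from real-world walking bouts: a
reproducible R implementation of the analysis pipeline used to derive
reference values for everyday walking in community-dwelling older
adults from a week of wearable-sensor monitoring.

## What it does, and for whom

Body-worn inertial sensors reduce a week of daily life to a stream of
detected **walking bouts**, each carrying duration, step count,
cadence (steps/min), walking speed (m/s), stride length (cm) and
stride duration (s). Researchers in gait analysis, geriatrics and
digital-health validation summarise such streams into **24 DMOs**
spanning five mobility domains — Amount, Pattern, Pace, Rhythm and
bout-to-bout Variability — and analyse how they vary with age, sex,
height and weight.

`dmobench` implements that pipeline end to end:

* **DMO engine** — bout-to-day assignment, wear-time validity
  (valid day: wear time strictly > 12 h), bout stratification by
  duration (> 10 / > 30 / > 60 s strictly; "shorter" bouts are
  (10, 30] s), the 24 daily DMOs, and weekly averaging over valid
  days (valid week: ≥ 3 valid days). Per day, a DMO is a sum, count,
  median, 90th percentile (the robust "maximum", linear-interpolation
  quantile), per-bout mean, or coefficient of variation
  COV = sd/mean (n−1 denominator, ≥ 2 bouts). The weekly table is a
  `DMOExperiment` (a `SummarizedExperiment`: 24 × participants assay,
  demographics in `colData`).
* **Reference statistics** — mean (sd), median (P25–P75) per DMO;
  skewness-gated log transform (|adjusted Fisher–Pearson skewness| > 2);
  ANCOVA subgroup comparisons (sex within age groups 65–74 / 75–84 /
  85–94 adjusted for height and weight; short vs tall within sex,
  split at the sex-specific median height, adjusted for age and
  weight); Benjamini–Hochberg FDR across the 24 DMOs of each stratum;
  two-sample Kolmogorov–Smirnov comparisons.
* **Age trends** — per-DMO, per-sex Gaussian GAMs
  `y = s(age) + β₁·height + β₂·bmi` with a penalized B-spline smooth
  (GCV-selected smoothing via `mgcv`), explained deviance (pseudo-R²),
  approximate age-term p-values, and partial-dependence curves with
  95% bands.
* **Structure** — age-stratified Pearson correlation matrices and
  principal-axis factor analysis with varimax rotation; DMOs are
  assigned to the factor with the largest absolute loading when it
  exceeds 0.4.
* **Synthetic cohort generator** — a calibrated simulator of
  demographics, wear intervals and per-bout records (kinematic
  identities `stride_duration = 120/cadence`,
  `speed = stride_length/100 / stride_duration` hold exactly), with a
  null mode and injectable age/sex/height effects. It is the test bed
  for every other module; see the methods vignette
  (`vignettes/dmobench-methods.Rmd`) for its assumptions and limits.

## Worked example

```r
library(dmobench)

coh <- generateCohort(syntheticConfig(), seed = 42)   # 200 adults x 7 days
se  <- computeCohortTable(coh$participants, coh$bouts, coh$wear)
#> computeCohortTable: 120 invalid day(s) removed; 0 participant(s) excluded
#> (<3 valid days); 200 retained
se
#> DMOExperiment: 24 DMOs x 200 participants
#>   age 65-94 y; 98 F / 102 M; mean valid days 6.4
#>   domains: Amount, Pattern, Pace, Rhythm, Variability

summarizeDMOs(se)[c(1, 2, 10, 11, 16), c("dmo", "unit", "mean", "sd")]
#>               dmo      unit     mean       sd
#>  walking_duration     h/day    1.576    0.437
#>           n_steps steps/day 8362.752 2320
#>       speed_short       m/s    0.621    0.069
#>        speed_long       m/s    0.777    0.081
#>       cadence_all steps/min   84.719    3.79
```

Participants walk about 1.6 h and 8,400 steps per day; speed in
shorter (10–30 s) bouts (0.62 m/s) is lower than in long (> 30 s)
bouts (0.78 m/s), the usual capacity gap between brief household
walking and sustained gait.

```r
sub <- buildSubgroupTables(se)
subset(sub, comparison == "height_within_sex" & stratum == "F" &
            dmo == "speed_long")
#> speed_long, females short vs tall: 0.738 (0.064) vs 0.804 (0.089),
#> FDR p = 0.0034
```

Taller women walk faster in long bouts even after adjusting for age
and weight — the generator injects a height effect on stride length,
and the ANCOVA machinery recovers it.

```r
gamAgeTrends(se, dmos = "speed_long")$summary
#>         dmo sex   n explained_deviance_pct  edf age_p stars
#>  speed_long   F  98                   52.9 2.88     0   ***
#>  speed_long   M 102                   62.5 1.00     0   ***

fitFactorModel(se)
#> Principal-axis factor model: 24 variables, 5 factors, n = 200
#>   variance explained: 29.3%, 28.9%, 24.7%, 3.8%, 2.1% (cumulative 88.8%)
```

The age smooth explains half the between-person variance in long-bout
speed, and five factors reproduce the expected domain structure of
the 24 DMOs.

`runPipeline(runConfig(...))` chains all stages and writes
`dmo_daily.csv`, `dmo_weekly.csv`, `reference_table.csv`,
`subgroup_sex.csv`, `subgroup_height.csv`, `gam_summary.csv`,
`gam_curves.csv`, `correlations_<agegroup>.csv`, `loadings.csv`,
`domain_assignment.csv`, a resolved `config_echo.yaml`, a stage log
and a markdown report; reruns with the same seed and config are
byte-identical. A thin CLI wrapper lives at
`inst/scripts/dmobench.R`.

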