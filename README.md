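# vfsector

Sector-wise trend analysis and forecasting of Humphrey 10-2 visual fields
in retinitis pigmentosa (RP).

## What it is for

RP destroys the peripheral visual field first, leaving a shrinking central
island that clinicians monitor with the Humphrey 10-2 test: 68 points in
the central 10°, each a total-deviation (TD) value in dB.  Predicting a
patient's future field from a short test series is hard because pointwise
linear regression (PLR — one OLS line of TD on time per point) is swamped
by test–retest noise, while a single global mean-trend (MS) misses focal
change.  `vfsector` implements the compromise, **sector-wise regression**:

1. Partition the 68 points into sectors.  Sectors can be learned from TD
   profiles with a from-scratch **HOPACH-PAM** clustering engine
   (partitioning around medoids inside a hierarchical
   ordering-and-collapsing tree, cluster numbers selected automatically by
   the mean median split silhouette, MSS), or taken from the two shipped
   reference maps: **S1** (24 concentric RP-style sectors, several
   straddling the horizontal midline) and **S2** (29 glaucoma-style
   sectors that respect the midline).  The shipped maps are synthetic
   reconstructions of the published maps' documented structure.
2. For each visit, average TD within each sector and allocate the mean to
   the sector's points; extrapolate each point's allocated series to the
   target date with OLS: `td_hat(p, t*) = a_p + b_p t*`.
3. Score forecasts by the mean absolute error (MAE, dB) over the 68
   points, and compare methods with a linear mixed model
   `mae ~ method + (1 | patient)` (patient as random effect, REML,
   Wald-type t test) with Benjamini–Hochberg correction across all
   6 method pairs × 7 sequence lengths.

Because no RP field dataset is public, the package also ships a calibrated
synthetic cohort generator (concentric loss surface
`TD(r,t) = s·t − L·σ((r − (r0 − v·t))/w)` with shared-per-visit plus
per-point Gaussian noise, floored at −35 dB) used by the tests and the
acceptance script.

## Worked example

```r
library(vfsector)
cohort <- simulate_cohort(cohort_config("testing", n_eyes = 40, seed = 2026))
cohort
#> vf_cohort: 40 eyes, 20 patients, visits per eye 10-10
tab <- evaluate_cohort(cohort)           # predict visit 10 from visits 1..n
cmp <- run_full_comparison(tab)
report_comparison(tab, cmp)
```

```
Mean absolute error when predicting the 10th VF
MAE (dB)        1-3      1-4      1-5      1-6      1-7      1-8      1-9
S1         7.2±2.7 4.7±2.0 3.4±1.2 2.9±1.1 2.6±0.8 2.3±0.5 2.1±0.3
S2         7.9±2.4 5.3±2.0 4.0±1.1 3.4±1.1 3.2±0.9 2.9±0.8 2.7±0.8
PLR       10.2±2.3 6.3±1.7 4.3±1.0 3.4±1.0 2.9±0.7 2.4±0.5 2.2±0.4
MS         7.1±3.4 6.2±3.0 5.7±2.6 5.6±2.5 5.5±2.4 5.5±2.5 5.4±2.5

Adjusted P values (linear mixed model, BH)
pair              1-3      1-4      1-5      1-6      1-7      1-8      1-9
S1 vs. S2         0.1      0.1   0.015*  0.0081*  <0.001*  <0.001*  <0.001*
S1 vs. PLR    <0.001*  <0.001*  <0.001*  0.0068*     0.06     0.22     0.65
...
*adjusted P < 0.05
```

Reading it: each cell is the mean ± SD MAE (dB) when the 10th field is
forecast from the first *n* visits (column `1-n`).  With only three
visits, sector-wise regression on the RP map (S1, 7.2 dB) clearly beats
PLR (10.2 dB) because sector averaging suppresses measurement noise; the
advantage shrinks as visits accumulate and is gone by `1-9`, where the
per-point fits have stabilised.  The RP-specific S1 map also outperforms
the glaucoma map S2 at longer sequences, and the global MS trend is
competitive only for the shortest series.  The p-value block gives the
BH-adjusted mixed-model contrasts for each method pair.

Other entry points: `hopach()` + `map_from_hopach()` to learn a sector
map from a training matrix (`split_train_test()`), `read_cohort()` /
`write_cohort()` for the documented CSV format,
`apply_reliability_filter()` for the ≥20 % fixation-loss / ≥15 %
false-positive exclusion rule, and a command-line wrapper
(`inst/cli/vfcluster.R`) with `simulate`, `cluster`, `predict` and
`evaluate` subcommands.

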