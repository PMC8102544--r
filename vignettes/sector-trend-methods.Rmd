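---
title: "Sector-wise trend analysis of 10-2 visual fields: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sector-wise trend analysis of 10-2 visual fields: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfsector)
```

## The problem

In retinitis pigmentosa (RP), photoreceptor degeneration destroys the
peripheral visual field first and leaves a shrinking central island.
Clinical monitoring relies on the Humphrey 10-2 test: 68 locations within
the central 10 degrees, each reported as a total-deviation (TD) value in dB
relative to age-matched normals.  Forecasting a patient's future field from
a short series of tests must balance two error sources: pointwise linear
regression (PLR, one OLS line per location) is unbiased but drowns in
test-retest noise when few visits are available, while a single global mean
trend (MS) is noise-robust but blind to focal change.  Sector-wise
regression is the compromise: average TD within anatomically coherent
sectors, regress the sector mean on time, and allocate the extrapolated
mean back to the sector's points.

`vfsector` implements the full workflow: deriving RP-specific sectors from
TD profiles by HOPACH-PAM clustering, the three forecasting methods, a
mixed-model accuracy comparison, and a synthetic RP cohort generator used
to validate all of it.

## Grid and data model

The 10-2 pattern is represented as the odd-degree lattice
$\{\pm1,\pm3,\pm5,\pm7,\pm9\}^2$ restricted to $x^2+y^2 \le 82$ -- the
unique circular cutoff on that lattice yielding exactly 68 points
(maximum eccentricity $\sqrt{82} \approx 9.06^\circ$).  Points are indexed
0-67 row-major from superior to inferior and, within a row, from temporal
to nasal.  Because the left-eye grid is defined as the right-eye grid with
$x$ negated *at the same index*, index $i$ is anatomically equivalent in
both eyes; mirror-imaging a left eye therefore reduces to relabelling,
which keeps TD vectors, sector maps and CSV files interoperable with one
canonical ordering.

Reliability filtering follows the usual device recommendation: a visit
with $\ge 20\%$ fixation losses or $\ge 15\%$ false positives (inclusive
thresholds) is discarded, and each eye's first-ever examination is dropped
as a familiarisation effect.  A naive "drop the first exam" step would not
be idempotent -- re-filtering an already-filtered cohort would eat a good
visit -- so the cohort carries a `first_exam_removed` provenance flag and
the step is skipped when it has already been applied.

## Sector derivation: HOPACH-PAM

Test points are clustered by their TD profiles across eyes (a 68 x n
matrix, one column per eye's earliest retained visit).  The distance
default is *cosangle*, $d = 1 - \cos\theta$ between profile vectors, the
conventional choice for profile-shape clustering; Euclidean and
correlation distances are available.  The clustering engine is a
from-scratch HOPACH (hierarchical ordered partitioning and collapsing
hybrid) built on PAM:

* **PAM.** BUILD initialisation plus SWAP steepest descent; for $n \le 10$
  items the medoid set is found by exhaustive enumeration, so small
  subproblems are solved to global optimality.  All ties break toward the
  lower item index, making every stage deterministic.
* **Model selection.** The number of children at every split is chosen by
  the mean median split silhouette (MSS): each cluster is tentatively
  re-split (PAM over $c = 2..\min(c_{max}, m-1)$ children, keeping the $c$
  with the best average silhouette), the median of the resulting split
  silhouettes summarises how much substructure the cluster still hides,
  and MSS is the mean of those medians.  Low MSS = homogeneous clusters.
  Clusters of one or two items cannot be split informatively and
  contribute 0.
* **Ordering and collapsing.** Clusters at each level are ordered by a
  deterministic greedy chain over medoid distances (start at the most
  extreme medoid, repeatedly append the nearest unplaced one).  When
  collapsing is enabled, the order-adjacent merge that most lowers the
  level MSS is applied repeatedly until no merge improves.
* **Tree and main partition.** The root chooses $k \in \{2..k_{max}\}$
  minimising MSS (ties to the smaller $k$); each cluster of three or more
  items is recursively partitioned the same way; recursion stops when all
  clusters have $\le 2$ items, when the new level raises MSS, or when
  collapsing undoes the refinement.  The *main partition* is the level
  with minimum MSS, ties to the shallowest level.

Defaults $k_{max} = c_{max} = 9$ follow HOPACH convention.  A consequence
of the MSS convention for tiny clusters is that deep levels with many
small clusters score well, so main partitions are fine-grained -- consistent
with sector maps in this field having 20-30 sectors for 68 points.  The
algorithm draws no random numbers; a `seed` argument is recorded in the
result's provenance only.

## Shipped sector maps

Two reference maps are installed under `inst/extdata/` and loaded with
`builtin_sector_map()`:

* **S1** (24 sectors): the RP-style map.  RP damage is concentric, so its
  sectors form rings, and the mid-peripheral band of sectors straddles the
  horizontal midline (crossing sectors include 6, 9, 11, 12, 14, 15, 16).
* **S2** (29 sectors): the glaucoma-style map.  Glaucomatous damage
  follows retinal-nerve-fibre-layer anatomy, which respects the horizontal
  raphe, so no S2 sector contains points on both sides of the midline.

Both files are **synthetic reconstructions**: they are built to satisfy
every documented structural property of the published maps (sector counts,
concentric vs hemifield organisation, the crossing-sector ids) but are not
transcriptions of the original figures, which are not redistributable.
Each file carries a provenance comment saying so.  `sector_structure()`
reports sizes, crossing sectors and eccentricity ranges, and the test
suite asserts the structural properties above.  Learned maps from
`hopach()` output are renumbered in reading order of their medoids
(descending $y$, then ascending $x$), since no canonical numbering rule
exists for new maps.

## Forecasting and evaluation

All three predictors are one function: `sectorwise_predict()` computes
per-visit sector means, allocates them to member points, fits one OLS line
per point and extrapolates to the target time.  `plr_predict()` is the
singleton-sector special case and `ms_predict()` the one-sector special
case -- these identities are bit-exact and tested as such.  Predictions are
deliberately *not* truncated or clamped to the instrument range: truncating
low sensitivities is not done by the standard progression-analysis tools
this workflow mirrors.  Accuracy is the mean absolute error (MAE) over the
68 points at the 10th visit.

`evaluate_cohort()` reproduces the standard validation design: every eye
has exactly ten visits; the 10th field is predicted from the first $n$
visits for $n = 3..9$ with each method (S1, S2, PLR, MS), giving a
complete eyes x methods x sequences MAE table.  `lmm_compare()` contrasts
two methods at one sequence length with a linear mixed model
`mae ~ method + (1 | patient)` fitted by REML -- the patient is the random
effect because both eyes of a patient contribute -- and reports the method
fixed effect with its Satterthwaite t-test p-value (a Wald-type test; in
the balanced one-eye-per-patient case it reduces exactly to the paired
t-test, which the tests verify to $10^{-3}$).  When the two methods'
errors differ by an exact constant the mixed model is degenerate (zero
residual variance) and the paired reduction is used directly.
`run_full_comparison()` runs all 6 method pairs x 7 sequence lengths = 42
comparisons and adjusts the whole family jointly by Benjamini-Hochberg
(`stats::p.adjust`); the family choice is configurable to per-pair because
the convention is not universal.

## The synthetic cohort generator

No RP visual-field dataset is bundled, so validation runs on a generative
model of concentric field loss.  The noiseless TD surface is

$$\mathrm{TD}(r, t) = s\,t - L\,\sigma\!\left(\frac{r - (r_0 - v\,t)}{w}\right),$$

with $\sigma$ the logistic function: a preserved island of radius $r_0$
shrinking at $v$ degrees/year, a peripheral scotoma of depth $L$ dB with
transition width $w$, and a uniform secular slope $s \le 0$, floored at
$-35$ dB (a dynamic-range proxy).  The logistic edge is a modelling
choice (differentiable, single interpretable width), not a published
formula.  Measurement noise has two components per visit: a global
fluctuation shared by all 68 points (default SD 1 dB) and independent
per-point noise (default SD 2 dB) -- magnitudes are stated assumptions, as
perimetric noise magnitudes for this population are not published,
exposed in the configuration.  The shared component is what makes sector
averaging genuinely useful, mimicking the short- and long-term
fluctuations of real perimetry.

Cohort-level defaults emulate the published cohort descriptions.  Two
eyes per synthetic patient share parameters through a latent patient
effect (inter-eye correlation 0.8) so the random-intercept model has
signal.  Visit intervals have mean 0.9 years (ten visits span about
8.1 years), with both within-eye jitter (SD 0.15 y) and between-eye
spread of the mean interval (SD 0.2 y) so the cohort-level span SD is
realistic (about 1.9 y).  The training calibration (858 eyes, age
51.3 +/- 15.7) centres the baseline MD proxy -- the unweighted mean of the
68 TD values, used throughout because the device's MD weighting is
proprietary -- near $-17.9$ dB; the testing calibration (196 eyes, age
47.7 +/- 12.1) centres it near $-16.4$ dB with a decline to about
$-21$ dB by the tenth visit.  Island radius and scotoma depth are
truncated normals (training: $r_0 \sim \mathcal{TN}(3.5, 4.6, [0, 14])$,
$L \sim \mathcal{TN}(32.5, 7, [8, 38])$) chosen once against those summary
targets.  A known limitation: the $-35$ dB floor censors the deepest
fields, so the simulated baseline-MD spread saturates near 9 dB, below
the published 10.5 dB; matching the spread would require a heavier-tailed
stage mixture than this single-surface model provides.  The generator
also does not emulate fixation instability artefacts, learning effects
beyond the dropped first exam, cataract-related diffuse loss, or genetic
subtype structure -- so passing validation here demonstrates correctness of
the machinery under a plausible RP-like data-generating process, not
clinical performance.

## What the validation shows

On the default 196-eye synthetic testing cohort, sector-wise regression
with S1 has lower mean MAE than PLR at three visits and the advantage
shrinks monotonically as visits accumulate, with PLR catching up by nine
visits -- the expected bias-variance crossover: sector averaging suppresses
noise when data are scarce, and its within-sector bias dominates once the
per-point fits stabilise.  MS is strongest with very short series and
worst with long ones, for the same reason taken to the extreme.  These
are asserted as directional Monte-Carlo properties, not as numeric
reproductions: the published MAE figures came from a clinical cohort that
is not deposited, and no synthetic calibration can legitimately reproduce
them digit-for-digit.

Problem sizes in the test-suite were chosen to keep the full suite fast
while leaving every property well-resolved: enumeration oracles use
$n \le 8$ items (100 seeded instances), the clustering toys 9-12 items,
the mixed-model oracle 20 simulated tables of 25 patients, and the
directional replication the full 196-eye default cohort.

## Numerical conventions

* Ties anywhere in clustering (distances, objectives, MSS, silhouettes)
  break toward the lower item/cluster index or the smaller $k$; repeated
  runs are bitwise identical.
* Silhouette conventions: singletons and all-zero ($a = b = 0$) cases
  score 0; size $\le 2$ clusters have split silhouette 0.
* OLS is closed-form; degenerate inputs (one visit, zero time variance,
  too-early target time) are errors, not warnings.
* Cohort CSVs are written with round-trip-exact double formatting, so
  write-read cycles are lossless; reliability thresholds are inclusive
  ($\ge$).
* The simulator consumes its own RNG stream under `set.seed(config$seed)`
  and restores the caller's state.
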