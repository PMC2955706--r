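---
title: "Timer and sizer control of the Chlamydomonas cell cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timer and sizer control of the Chlamydomonas cell cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chlamycycle)
```

## The model

*Chlamydomonas reinhardtii* proliferates by multiple fission: a long
interdivision phase of photosynthetic growth is followed by a short
division phase in which the mother runs one or two rounds of mitosis back
to back and releases 2 or 4 daughters. Light is the only energy source, so
the growth side of the cycle is fully controlled by the photosynthetically
active radiation (PAR) a cell receives. `chlamycycle` implements a
quantitative control model for this cycle with three interacting rules, a
measurement pipeline that extracts the model's quantities from single-cell
volume time series, a contour-based volumetry module for micrographs, and
a seeded generator of synthetic cohorts.

**Growth.** During the interdivision phase cell volume grows
exponentially, $V(t) = V(0)\,e^{\mu t}$, at a rate set by light:

$$\mu(P) = \mu_{max}\,\frac{P - P_0}{K + P - P_0}, \qquad P > P_0,$$

and $\mu = 0$ at or below the compensation point $P_0$. In darkness cells
neither grow nor shrink. The shifted rectangular hyperbola is the simplest
saturating form consistent with three observed facts: no net growth at
0.2 µmol m⁻² s⁻¹, a saturation plateau near 300 µmol m⁻² s⁻¹, and an
eight-fold change in growth rate (equivalently, in interdivision duration)
between PAR 10 and PAR 200. The default calibration pins $K$ exactly to
the eight-fold constraint with $P_0 = 0.2$, and anchors the absolute scale
at $\mu(200) = 0.14\,h^{-1}$, i.e. an interdivision duration of roughly
10 h under bright continuous light. That anchor is a calibration choice of
this package — absolute durations are not constrained sharply by the
population statistics the model targets — and it is configurable through
`default_growth_calibration(mu_at_200 = ...)`.

**Interdivision timer.** Division-phase entry is triggered when an
internal signal $s(t) = \int_0^t r(\tau)\,d\tau$ reaches a fixed threshold
$s^\ast$ (default $\log 4.1 \approx 1.411$). The accrual rate $r$ switches
at commitment:

* before commitment, $r$ is the instantaneous growth rate, so
  $s = \log V/V(0)$ exactly and nothing accrues in darkness;
* after commitment, $r$ is the growth rate *memorised at the moment of
  commitment*, and accrual continues even in darkness or under a changed
  PAR.

This single accrual process reproduces every reported invariance at once:
under continuous light $\mu T = s^\ast$ identically; for a committed cell
switched to darkness, entry occurs at $T = s^\ast/\mu_L$ regardless of
when the light ended; for an uncommitted cell, a dark interval of any
length simply shifts entry by that length, so
$\mu_L (T - T_{dark}) = s^\ast$; and for a PAR step before commitment the
two rates accrue additively, $\mu_{L1}T_{L1} + \mu_{L2}T_{L2} = s^\ast$.
The observed products are 1.4 ± 0.2 under the one-level regimes and
1.5 ± 0.2 under the two-level regime; the difference is well inside the
dispersion, so a single threshold is used, set to $\log 4.1$ so that the
continuous-light entry ratio is exactly the observed 4.1.

**Commitment sizer.** A cell passes the primary arrest point — the early
G1 control point analogous to the yeast "start" — only once its volume
reaches twice its initial volume while growing. Uncommitted cells deprived
of light arrest indefinitely (observed for at least 48 h); committed cells
divide on schedule even in darkness.

**Mitotic sizer.** The final-to-initial volume ratio at entry sets the
daughter number: below 2 no division (the gate is shared with the
commitment ratio), between 2 and 2.9 one round of mitosis (2 daughters),
at or above 2.9 two rounds (4 daughters). Odd daughter numbers never
occur. The observed two-versus-four transition is a band rather than a
sharp cut — roughly 2.8–3.1 under light–dark, 2.9 under
light–dark–light, 2.7 under the PAR step — so the default deterministic
cutpoint is 2.9, with an optional stochastic mode
(`cycle_params(stochastic_bands = TRUE)`) that draws per-cell cutpoints
uniformly from the indeterminate bands 1.8–2.2 and 2.7–3.1. The lower
observed bound is printed both as "below 1.8" and as the doubling gate;
the deterministic default ties it to the commitment ratio 2, and the
1.8–2.2 band is available only in stochastic mode.

**Division phase.** After entry the cycle appends a fixed subphase
schedule — shrinkage, rotation, first mitosis, second mitosis (four
daughters only), mitosis completion — whose durations do not depend on
light. The magnitudes (0.3/0.3/0.5/0.5/0.4 h) are plausible placeholders,
not measured constants; what the model asserts, and what the tests check,
is their PAR-independence. The final volume is partitioned equally among
daughters, and a followed daughter starts at $V_{final}/n$ — the quarter
convention for four-fold fission. (Freshly hatched daughters measure
somewhat larger than a quarter of the mother's maximum — 87 µm³ against
69 µm³ in one worked example — because growth resumes inside the mother
wall before hatching; the quarter convention is used for lineage seeding,
and the analysis pipeline measures $V(0)$ from the first recorded
samples.)

## Simulation

Within each constant-PAR segment both $\log V$ and $s$ are linear in
time, so `simulate_cycle()` solves commitment and firing times in closed
form segment by segment; there is no numeric ODE stepping and no
tolerance to tune. This makes the headline identities exact: under
continuous light $\mu T$ equals the threshold to machine precision at
every PAR, and `T(10)/T(200)` is exactly 8 under the default calibration.
A schedule whose final segment ends at a finite time is implicitly
extended by darkness; a cell that never commits in such a schedule
arrests, which is reported (`division_number = 0`, `NA` entry time)
rather than raised.

Noise enters only through seeded runs: one lognormal multiplier on the
growth rate (`cv_mu`) and one on the timer threshold (`cv_threshold`) per
cell, plus per-sample multiplicative measurement noise
(`cv_measurement`). All randomness flows from explicit integer seeds and
never disturbs the caller's RNG stream.

```{r}
res <- simulate_cycle(schedule_LL(200))
res
```

## The synthetic cohorts

`generate_cohort()` emulates on-chip single-cell recordings: initial
volumes are lognormal with mean 79.7 µm³ and SD 12.6 µm³ (the observed
distribution), volumes are sampled every 30 s by default, and at
division-phase entry the trajectory carries the morphological signature
used for detection — a 10% volume drop over the shrinkage subphase
followed by a plateau until hatching. The drop magnitude is a rendering
convention for detector testing, not a measured value.

The default noise levels — `cv_mu = 0.25`, `cv_threshold = 0.1`,
`cv_measurement = 0.03`, `v0_cv = 12.6/79.7` — are calibrated once so
that cohort-level dispersion matches the observations: the coefficient of
variation of the interdivision duration lands in the observed 21–38%
band (the two between-cell CVs combine to a population CV of about 27%)
and the dispersion of the $\mu T$ product is about ±0.2. Only the
initial-volume mean and SD are measured values; the rest are model
calibration.

What the generator does *not* emulate: within-cell temporal fluctuations
of the growth rate (only endpoint statistics are observed, so measurement
noise is i.i.d. multiplicative), cell-wall optics, neighbouring cells, or
any molecular state. Passing tests therefore demonstrate internal
consistency of model plus pipeline under these assumptions, not accuracy
on real micrograph series.

## The measurement pipeline

`analyse_trajectory()` mirrors how the observed quantities were defined:

1. **Division-entry detection.** Entry is visible morphologically; in a
   volume series the only available proxy is a sustained drop. The
   series is smoothed with a running median (window 0.5 h and at least 15
   samples — a raw running maximum over thousands of noisy samples is
   biased upward and would fake early drops), and a drop is called when
   smoothed values stay below 95% of the smoothed running maximum for at
   least `min_samples` and one full smoothing window. The reported entry
   time is the onset of the decline, found by walking back to where the
   smoothed series stops strictly declining, with ties broken on the raw
   series so that a dark plateau before entry is not crossed. On
   noiseless data this lands on the true entry sample; the record must
   extend about one smoothing window past shrinkage onset.
2. **Per-light-period rates.** `fit_exponential()` regresses
   $\log V$ on time separately within each illuminated interval clipped
   to the interdivision phase; dark intervals are excluded. Log-scale
   fitting matches the multiplicative error structure and is exact on
   noiseless data.
3. **Products.** `compute_products()` reports the raw product
   $\mu_{L1} T$, the dark-adjusted product $\mu_{L1}(T - T_{dark})$, and,
   for two light periods, the additive accrual $\sum_i \mu_i T_i$; with
   no darkness the dark-adjusted product equals the raw one.
4. **Division number.** From generator annotations when present,
   otherwise by applying the mitotic sizer to the measured ratio; endpoint
   volumes are 3-sample medians so that window growth stays below the
   noise.
5. **Cohort summary.** Sample means, SDs (n − 1), CV of $T$ in percent,
   and the daughter-number tally. Cells that never divide contribute to
   the tally only.

```{r}
spec <- cohort_spec("LL", n_cells = 26, schedule_params = list(par = 200),
                    sampling_interval = 1 / 60, seed = 1)
summarise_cohort(analyse_cohort(generate_cohort(spec)))
```

## Image volumetry

Cells are axisymmetric about their long axis, so volume can be estimated
from a single cross section: threshold (Otsu by default, or a fixed
value), fill holes, keep the largest connected component, take principal
axes from second moments (for a solid ellipse the per-axis SD is a
quarter of the full axis length), and integrate the half-width profile as
a solid of revolution, $V = \pi \int h(x)^2\,dx$, by the trapezoidal rule
at pixel resolution.

The prolate-spheroid closed form $V = \tfrac{4}{3}\pi (L_a/2)(L_b/2)^2$
is provided as the analytic reference; for a perfect ellipse the two
estimators agree within discretisation error (< 1% with ≥ 200 px along
the long axis; 2–3% at typical resolutions, commensurate with 0.2 µm
optics). Sub-pixel accuracy is deliberately not attempted. Both the
profile-rotation estimator and the spheroid form are exposed, since
either could reasonably serve as the primary definition of "measured
volume".

```{r}
img <- generate_cell_image(La = 10, Lb = 7, orientation = 0.5,
                           pixel_size = 0.05, dim = c(400L, 360L))
measure_cell_volume(img)
spheroid_volume(10, 7)
```

## Numerical and design choices

* **Closed-form events, no integrator.** Commitment and firing are roots
  of linear equations per segment; ties (e.g. commitment exactly at a
  segment boundary) resolve in favour of firing first, then commitment.
* **Memorised rate.** Whether the post-commitment rate is the
  instantaneous rate at commitment or the average over the first light
  period is indistinguishable under piecewise-constant PAR; the rate of
  the segment in which commitment occurred is used.
* **Single timer threshold.** $\log 4.1$ for all regimes; the 1.4 vs 1.5
  difference between one- and two-level regimes is far below the ±0.2
  dispersion.
* **Condition labels from the schedule, not the data**: one light level
  throughout is LL, light into terminal darkness LD, light–dark–light at
  equal PAR LDL, two light levels with no darkness L1L2.
* **Problem sizes.** Tests and the acceptance script use cohorts of 26
  cells per PAR at 1-minute sampling and 200-cell recovery experiments —
  the observed cohort sizes, at a sampling density that keeps estimator
  error well below between-cell dispersion.
* **Degenerate inputs.** Empty foregrounds, disconnected masks, all-zero
  profiles, shrinking "growth" endpoints, non-contiguous schedules and
  malformed CSV/JSON all raise typed errors naming the offence; an
  arrested lineage truncates with a report instead.

## Known limitations

* Behaviour of uncommitted cells re-illuminated after very long darkness
  (beyond ~9 h) is an extrapolation; the model simply resumes accrual.
* The light-response curve above PAR 200 is an extrapolation of the
  hyperbola; only the region up to the plateau is constrained.
* The division-entry detector needs the volume record to continue about
  one smoothing window past shrinkage onset, and its entry times are
  quantised to the sampling grid.
* Division subphase durations are placeholders; only their
  light-independence is meaningful.
* The generator's trajectories are idealised (exponential growth, clean
  plateaus); real micrograph series contain tracking artefacts and shape
  changes that the pipeline has not been validated against.
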