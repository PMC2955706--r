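# chlamycycle

Simulation and single-cell analysis of cell-cycle control in the green
alga *Chlamydomonas reinhardtii* under arbitrary light schedules.

*Chlamydomonas* divides by multiple fission: a long interdivision phase of
light-driven growth is followed by a short division phase producing 2 or 4
daughters. For researchers modelling how such cells coordinate growth with
division — or benchmarking single-cell trajectory pipelines — this package
implements a complete quantitative control model and the measurement
machinery around it:

* **Growth law.** Exponential volume growth `V(t) = V(0)·exp(μt)` with a
  saturating light response `μ(P) = μmax·(P − P₀)/(K + P − P₀)` above the
  compensation point `P₀` (PAR in µmol m⁻² s⁻¹); growth arrest in
  darkness. The default calibration fixes the eight-fold rate change
  between PAR 10 and 200 exactly.
* **Interdivision timer.** Division-phase entry when the accrued signal
  `s(t) = ∫ r dτ` reaches a threshold `s* = log 4.1 ≈ 1.411`: before
  commitment `r` is the instantaneous growth rate (so `s = log V/V(0)`);
  after commitment, the rate memorised at commitment, accruing even in
  darkness. One mechanism reproduces the observed invariances
  `μ·T = 1.4`, `μ_L·(T − T_dark) = 1.4` and
  `μ_L1·T_L1 + μ_L2·T_L2 ≈ 1.5`.
* **Commitment sizer.** A cell can only ever divide after doubling its
  initial volume in the light (`V/V(0) ≥ 2`); uncommitted cells arrest in
  darkness indefinitely.
* **Mitotic sizer.** The final-to-initial ratio maps to daughter number:
  `< 2 → 0`, `[2, 2.9) → 2`, `≥ 2.9 → 4`; never odd.
* **Trajectory analysis.** Division-entry detection from the shrinkage
  signature, per-light-period rate estimation, timer products, division
  classification and cohort summaries.
* **Image volumetry.** Threshold → contour → principal axes → solid of
  revolution `V = π ∫ h(x)² dx`, with the prolate-spheroid closed form
  `(4/3)π(La/2)(Lb/2)²` as analytic reference.
* **Synthetic data.** Seeded cohorts of noisy volume trajectories under
  the four illumination regimes (LL, LD, LDL, L1L2) with full ground-truth
  annotations, and synthetic micrographs with known geometry.

## Worked example

Simulate one noiseless cell under continuous light at PAR 200:

```r
library(chlamycycle)
res <- simulate_cycle(schedule_LL(200))
res
#> Cell cycle: division-phase entry at T = 10.078 h
#>   V(0) = 79.7 um^3, V(T) = 326.8 um^3 (ratio 4.10)
#>   mu (first light period) = 0.1400 /h; mu*T = 1.411
#>   daughters: 4 x 81.7 um^3
```

The cell grows at 0.14 h⁻¹, enters the division phase after 10.08 h at
exactly 4.1 times its initial volume (the timer identity `μ·T = log 4.1`),
and splits into four daughters of a quarter of its final volume each.

Generate a noisy cohort like an on-chip experiment and push it through the
analysis pipeline:

```r
spec <- cohort_spec("LL", n_cells = 26, schedule_params = list(par = 200),
                    sampling_interval = 1/60, seed = 1)
summarise_cohort(analyse_cohort(generate_cohort(spec)))
#> Cohort of 26 cells (26 divided)
#>   T     : 10.79 +/- 2.40 h (CV 22.2%)
#>   mu*T  : 1.45 +/- 0.16
#>   V(T)/V(0): 4.09 +/- 0.68
#>   daughters: 0 -> 0, 2 -> 0, 4 -> 26
```

The recovered product stays near 1.4 with a dispersion of about ±0.2, and
the duration CV lands in the observed 21–38% band, while every cell
produces four daughters — exactly the continuous-light phenotype.

Measure a synthetic micrograph:

```r
img <- generate_cell_image(La = 10, Lb = 7, orientation = 0.5,
                           pixel_size = 0.05, dim = c(400L, 360L))
measure_cell_volume(img)
#>   area_um2    La_um    Lb_um volume_um3 volume_spheroid_um3
#> 1   54.925 9.998388 6.994392   256.1362            256.1112
spheroid_volume(10, 7)   # ground truth: 256.56 um^3
```

Both the profile-rotation estimate and the spheroid form recover the true
volume within a fraction of a percent at this resolution.

See `vignettes/cell-cycle-control.Rmd` for the model, its assumptions and
the design decisions.

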