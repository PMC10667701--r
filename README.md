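# physhab

Quantitative analysis of habituation experiments in the plasmodium of the
true slime mold *Physarum polycephalum*.

In these experiments a plasmodium sits on a nutrient start block and must
cross an 18 × 18 mm agar bridge — plain agar for controls, agar laced with
0.5 mM quinine (an aversive alkaloid) for the test condition — to reach a
goal block, once a day over four days of training plus a fifth day of
memory-manipulation probes.  The raw observables are time-lapse
transmitted-light image stacks (5-min frames for behaviour, 5-s frames over
10 min for thickness oscillations, 0.06–0.08 mm/px).  `physhab` turns those
stacks into the study's quantitative indices and runs the associated
statistics, for researchers analysing this kind of assay or building on its
methods:

* **Behaviour** — footprint area on the bridge at crossing completion
  (background subtraction at stage time *t*₀, thresholding, binarisation,
  pixel counting) and crossing speed
  *v* = *L* / (*t*ₑ − *t*₀) with *L* = 18 mm, normalised by the same-day
  control mean.
* **Tube orientation** — 2-D FFT power spectrum of a square goal-block
  crop; each retained spectral bin contributes its direction angle (folded
  to [0°, 180°), the spectrum being point-symmetric) weighted by power; the
  characteristic angle is the mode of the weighted kernel density; spectral
  angles are orthogonal to the physical tube direction and are converted by
  a quarter turn at reporting time.
* **Morphology** — a day's network is a *tree* when every characteristic
  angle deviates < 45° from the advancing direction and a *mesh* otherwise;
  4-day trajectories map to daily-change Types 0–5 (Type 0 tree throughout,
  Types 1–3 mesh from Day 4/3/2, Type 4 mesh throughout, Type 5 other).
* **Thickness oscillation** — a 320 × 320 px start-block ROI averaged over
  10 × 10 px blocks (32 × 32 grid), lowess-smoothed; periods are successive
  peak gaps, the block period *T* is the histogram mode, ω = 2π/*T*; blocks
  above half the Nyquist frequency (*f*ₙ = 0.1 Hz at 5-s sampling, cutoff
  2π·0.05 ≈ 0.3142 rad/s) are omitted as noise; the sample value is the
  median over retained blocks, normalised by the same-day control median.
* **Connection typing** — tubes spanning the bridge from start to goal are
  skeletonised and counted: *n* (0), *s* (1), *d* (2), *t* (≥ 3).
* **Statistics** — Shapiro (normality) and Bartlett (equal variance) gate
  at α = 0.05; if neither rejects, Dunnett many-to-one tests against the
  reference day, otherwise Steel rank tests; one-sided Mann–Whitney for
  tree-vs-mesh contrasts; tiers \* *p* < 0.1, \*\* *p* < 0.05,
  \*\*\* *p* < 0.01.
* **Synthetic data** — seeded generators for tube-network images with a
  known orientation mixture, bridge-crossing movies with known *t*ₑ and
  footprint area, oscillation movies with a programmed period field, and
  study tables with programmed day × condition effects, so every stage is
  verifiable without raw microscopy data.

## Worked example

```r
library(physhab)

# a goal-block network with one orientation mode, 110 deg in the image frame
net <- make_tube_network_image(tube_network_spec(
  data.frame(angle_deg = 110, weight = 1), n_tubes = 40, seed = 7))
ca <- characteristic_angle(power_spectrum_angles(net$image))
tube_angle_from_spectral(ca$peak_angles_deg[1])
#> [1] 110

# crossing behaviour on a simulated 18-mm bridge movie (0.18 mm/min)
mv <- make_crossing_movie(crossing_movie_spec(0.18, footprint = "string", seed = 1))
roi <- bridge_roi(0, 0, 288, 288, far_edge = "top")
st <- detect_crossing_times(mv$stack, roi)
st
#> <stage_times: t0 = 0 (frame 3), te = 100 min (frame 23)>
crossing_speed(18, st)
#> [1] 0.18

# thickness oscillation: two-region period field, 100 s / 150 s
pf <- matrix(100, 32, 32); pf[, 17:32] <- 150
osc <- make_oscillation_movie(oscillation_movie_spec(pf, noise_sd = 6, seed = 3))
map <- oscillation_map(grid_mean_series(osc$stack))
sample_frequency(map)
#> [1] 0.05308208

# gated day-wise contrasts on a table with a programmed quinine area drift
tab <- make_study_table(study_table_spec(
  n_per_cell = 15, day_effects = list(quinine = list(area = c(0, 2.5, 5, 7.5))),
  seed = 31))
run_study_contrasts(tab, "area")
#> # A tibble: 6 × 6
#>   index condition contrast       test             p tier
#>   <chr> <chr>     <chr>          <chr>        <dbl> <chr>
#> 1 area  control   Day 2 vs Day 1 Dunnett 0.994      ns
#> 2 area  control   Day 3 vs Day 1 Dunnett 0.420      ns
#> 3 area  control   Day 4 vs Day 1 Dunnett 0.998      ns
#> 4 area  quinine   Day 2 vs Day 1 Dunnett 0.00389    ***
#> 5 area  quinine   Day 3 vs Day 1 Dunnett 0.0000474  ***
#> 6 area  quinine   Day 4 vs Day 1 Dunnett 0.00000361 ***
```

The recovered tube angle equals the programmed 110°; the crossing time is
the construction-forced 18 mm / 0.18 mm min⁻¹ = 100 min; the oscillation
median 0.0531 rad s⁻¹ sits between the two programmed region frequencies
2π/100 = 0.0628 and 2π/150 = 0.0419; and only the condition with the
programmed drift shows significant day contrasts.

## Analysis workflow

The `analysis/` scripts run the pipeline as a narrative sequence over
simulated study data, writing tables under `results/`:

1. `01_simulate.R` — movies, day stacks, study table (with ground truth)
2. `02_behavior.R` — crossing times, areas, normalised speeds
3. `03_orientation_morphology.R` — angle time courses, tree/mesh states,
   daily-change types
4. `04_oscillation.R` — block frequency map and sample median
5. `05_connection.R` — connection typing and the morphology cross-tab
6. `06_stats.R` — gated Dunnett/Steel contrasts and tiers

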