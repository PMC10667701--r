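---
title: "Methods: quantifying transport-network morphology and habituation behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying transport-network morphology and habituation behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physhab)
```

## The system and the measurement problem

A plasmodium of *Physarum polycephalum* placed on a nutrient start block
crosses an 18 × 18 mm agar bridge to a goal block once a day.  When the
bridge contains 0.5 mM quinine, the plasmodium initially crosses slowly
along a thin string-like path; over repeated daily exposure it crosses
faster and spreads wider — a habituation-like behavioural change.  In
parallel, the transport-tube network the plasmodium builds on the goal
block changes from a *tree* (tubes nearly parallel to the advancing
direction) to a *mesh* (tubes in several directions), and the thickness
oscillation that drives shuttle streaming changes frequency.

The package quantifies all of these from 8-bit transmitted-light image
stacks: behaviour at 5-min frame intervals, oscillation at 5-s intervals
over 10 min, pixel size around 0.06–0.08 mm (the generators default to
0.0625 mm/px, the mid-range).  Two clock conventions are used throughout:
*stage time* *t* starts at *t*₀ = 0 when the plasmodium begins to cross and
reaches *t*ₑ when it touches the bridge edge adjacent to the goal; *network
time* *t*ₙ counts backwards to 0 at the end of the network-formation phase,
and the day's final network state is read from the window
*t*ₙ ∈ [−300, 0] min.

## Behavioural indices

**Area.**  The frame at *t*₀ is the background; the absolute difference to
the frame at *t*ₑ is thresholded and binarised, and the area is the
foreground pixel count inside the bridge ROI times the pixel area.  The
threshold policy is configurable: Otsu's method on the difference image by
default, or a fixed intensity.  Otsu is the right default when foreground
and background coexist in the ROI, but it has a genuine degenerate case —
a plasmodium covering the entire bridge yields a near-constant difference
image with nothing to separate, where only the fixed override is
meaningful.  Whether the original analyses used a global or per-image
threshold is not documented; both are expressible here.

**Crossing times.**  Detection uses a single global threshold taken from
the frame with the strongest difference signal, so empty early frames stay
empty.  *t*₀ is declared one frame before foreground first exceeds a
20-connected-pixel guard (the front is at the entry edge, i.e. invisible to
background subtraction, when crossing actually begins; the guard suppresses
noise-triggered starts).  *t*ₑ is the first frame whose foreground touches
the far-edge line of the ROI.  A front that already touches the far edge
when it first becomes visible leaves the crossing time unbounded below and
raises an error; a front that never reaches it returns a "not crossed"
signal rather than a number.  On generated movies the recovered speed is
exact to one frame interval.

**Speed.**  *v* = 18 mm / (*t*ₑ − *t*₀).  Day-to-day environmental effects
are removed by dividing by the mean speed of the same-day control samples
(mean, not median, for speeds; the oscillation index below uses the control
median).  Applied to the control group itself this yields exactly 1, which
is also the reference line drawn in the figures.

## Tube-orientation analysis

The goal crop is mean-centred, multiplied by a 2-D Hann window, and
Fourier-transformed.  Without the taper, the sharp image borders of a
nonperiodic scene leak power along the frequency axes and bias the angle
distribution toward 0°/90°; with it, single-orientation synthetic networks
are recovered to well under 1°.  Each spectral bin inside a radial band
contributes its direction angle atan2(−*f*ᵣ, *f*\_c), folded to [0°, 180°)
because the power spectrum is point-symmetric, weighted by its power.  The
default band keeps wavelengths between 4 px (safely above the 2-px sampling
limit) and a quarter of the crop side (excluding near-DC structure); both
ends are configurable because the original plugin settings are unknown.

The **characteristic angle** is the mode of the weighted kernel density of
these angles.  The density is estimated on data replicated at ±180° so the
periodic support has no boundary artefact, with bandwidth from Silverman's
rule applied to the weighted sample (effective sample size
(Σw)²/Σw², circular standard deviation via the doubled-angle
representation), clamped to [1°, 15°].  All local maxima reaching 25% of
the global maximum count as peaks, sorted by density with ties broken
toward the smaller angle.  The 25% prominence floor is the smallest value
that still suppressed spurious secondary peaks on single-mode synthetic
networks while keeping both modes of balanced two-mode networks; it is a
package choice, as the original work estimated densities but did not report
an acceptance rule.

A physical ridge oriented at θ concentrates spectral power along θ + 90°,
so spectral angles are converted to tube angles by one quarter-turn,
applied exactly once at reporting time in `orientation_time_course()`.
Reported angles are relative to the advancing direction of the plasmodium.
The figures of the original study are ambiguous about which frame their
numeric angles are plotted in; here the convention is explicit and the
correction is a single, logged step, so either reading can be reproduced by
toggling it.

Per frame of network time, the peak angles and densities form the
characteristic-angle series; over the final-state window the peaks are
pooled, density-weighted, and re-estimated to give the day's characteristic
angle(s).

## Tree/mesh classification and daily types

A day is a **tree** when every characteristic peak angle deviates less than
45° (acute deviation) from the advancing direction, and a **mesh**
otherwise; a single oblique peak at exactly 45° is mesh, since "< 45°" is
the parallel criterion.  The original classification was done manually and
blindfolded; this deterministic rule replaces it and retains the evidence
angles for audit.  Four-day sequences map to daily-change types: the five
monotone tree→mesh sequences give Types 0–4 (Type 1–3 = mesh from Day
4/3/2, respectively), and the remaining eleven sequences are Type 5
("other changes").  Missing days raise an error rather than defaulting to
Type 5, because a sequence with gaps is not evidence of a non-monotone
change.

## Thickness-oscillation mapping

The 320 × 320 px start-block ROI is averaged over 10 × 10 px blocks,
giving 1024 series of length 121 (10 min at 5 s, inclusive of the *t* = 0
frame; whether the original recordings held 120 or 121 frames is unstated,
and the inclusive convention is assumed).  Each series is smoothed by
lowess with span 0.1 of the window (≈ 60 s) — wide enough to suppress
frame-to-frame noise, narrow enough to preserve 60–200 s oscillations.
Periods are the gaps between successive strict local maxima whose
topographic prominence reaches 10% of the series' interquartile range
(plateaus take their left edge).  The block period *T* is the mode of the
period histogram at one frame-interval bin width, ties going to the longer
period — conservative against the noise cutoff; ω = 2π/*T*.  Blocks with
ω above half the Nyquist frequency (f_n = 0.1 Hz at 5-s sampling, cutoff
2π·0.05 ≈ 0.3142 rad/s) or with fewer than two peaks are omitted with a
recorded reason, and retained + omitted always sums to 1024.  The sample
value is the median ω over retained blocks.  Transmitted intensity falls as
thickness rises, but period estimation is sign-agnostic, so no inversion is
applied.

## Connection typing

Tubes are binarised by their absolute deviation from the median background
level (making the count invariant to inversion and uniform brightness
shifts), skeletonised by Zhang–Suen thinning with the boundary rows
replicated beforehand so skeleton ends stay anchored, and labelled with
8-connectivity.  Only skeleton components spanning the full bridge — from
the entry-side boundary to the goal-side boundary — count as connections: a
plasmodium merely sitting on the bridge is type *n*.  The count is the
number of distinct midline crossings by spanning components, merging
crossings closer than three tube widths (default 9 px) so junction spurs do
not inflate it.  An automatic threshold on a tube-free, noise-only bridge
will happily split the noise, so binarisation additionally requires the
foreground/background mean separation to exceed a contrast floor (20
intensity units) before anything counts as tube signal.  Counts map to
types *n*/*s*/*d*/*t* = 0/1/2/≥3; whether faint partial strands should
count was not documented, and the spanning-path rule is the package's
decision.

## Statistical workflow

For each family of day-wise groups, Shapiro–Wilk is applied per group and
Bartlett across groups at a gate level of α = 0.05 (the original work
names the tests but not the level; per-group Shapiro is assumed).  If
nothing rejects, Dunnett many-to-one comparisons (via `multcomp`) are run
against the reference group — Day 1 for the Days 1–4 scheme, the intact
group for the Day-5 scheme; otherwise the Steel test, the nonparametric
analogue.  Steel is implemented in-package: each treatment is compared to
the reference by a pairwise rank sum with tie-corrected variance, and the
familywise adjustment evaluates the multivariate normal distribution of the
standardized statistics with correlation √(nᵢnⱼ/((n₀+nᵢ)(n₀+nⱼ))); when any
group has fewer than 6 observations the package falls back to
Bonferroni-adjusted exact Wilcoxon tests, a documented conservative choice
(the original critical-value tables are impractical to embed).  With a
single comparison the statistic reduces to the normal-approximation
rank-sum test, which is verified against `wilcox.test` in the suite.
Two-group morphology contrasts use the Mann–Whitney test, exact where
sample sizes and ties permit.  Significance tiers are \* *p* < 0.1,
\*\* *p* < 0.05, \*\*\* *p* < 0.01.  One-sided directions are used where
the study's figure captions state them; two-sided is the default.

Calibration at the study's typical cell size (n = 15, four groups, 1000
null tables) gives familywise type-I error near the nominal 0.05 for both
branches, and power above 0.9 for a 1.5-SD Day-4 shift; the acceptance
script recomputes both.

## What the synthetic data does and does not emulate

The generators reproduce the statistical and optical structure the analysis
relies on: dark Gaussian-profile tube segments (σ = width/2.355, giving the
spectrum a realistic band-limited ridge) on a bright background with
additive Gaussian noise; a binary footprint advancing at constant speed,
blurred and darkened onto the background, which makes *t*₀/*t*ₑ detection
well-posed and forces the ground truth *t*ₑ = length/speed (required to be
an integer number of frames); per-block sinusoidal intensity modulation;
and study tables with additive day × condition effects under a normal or
lognormal family.  Defaults follow the study's stated conditions (18-mm
bridge, 5-min and 5-s sampling, 320-px ROI, 10-px blocks); oscillation
periods default to the 60–200 s range, chosen as physiologically plausible
rather than taken from a reported value.

They do **not** simulate plasmodial biophysics: no tube-adaptation
dynamics, no shuttle streaming, no growth model, no spatial phase waves,
and no coupling between behaviour, morphology and frequency other than what
a study-table spec programs in.  Passing recovery tests therefore
demonstrates that the measurement pipeline is correct and well-calibrated
on data matching its assumptions — not that the biological conclusions
would replicate on new organisms.

## Numerical choices and degenerate inputs

* Angles live on [0°, 180°); all comparisons use acute deviation, so 179°
  and 1° are 2° apart.
* A constant image has no non-DC power and yields an *empty, flagged*
  distribution; estimating a characteristic angle from it is an error, not
  a number.
* All-identical statistical groups return p = 1 (no evidence), and the
  degenerate all-tied two-group rank test does the same.
* Period-histogram ties take the longer period; density-peak ties take the
  smaller angle.
* Generators clamp intensities to [0, 255] after noise and are
  bit-reproducible for a fixed seed; ground truth is returned from the same
  draw, never re-derived stochastically.

## Problem sizes used in the checks

The test-suite and acceptance runs use 192–256 px network images (40–90
tubes), 20-seed cohorts for morphology and connection recovery, the full
32 × 32 × 121 oscillation grid, and 400–1000 simulated tables for power and
calibration.  These sizes keep every recovery property measurable with
comfortable margins while the whole suite runs in minutes on one core.

## Known limitations

* The FFT orientation estimate assumes roughly straight tubes at the band's
  length scale; strongly curved tubes spread their power over a range of
  angles and can merge adjacent density peaks.
* Connection counting reads crossings at the bridge midline of spanning
  skeletons; two tubes that merge exactly at the midline are counted once.
* The Steel implementation relies on the large-sample multivariate normal
  approximation above the n ≥ 6 threshold; very heavy ties at small n push
  it to the conservative fallback.
* Crossing-time resolution is one frame interval (5 min at the default
  cadence), which bounds the accuracy of every speed downstream.
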