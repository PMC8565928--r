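---
title: "Generative theta-sweep models and how the pipeline measures them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative theta-sweep models and how the pipeline measures them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
library(thetasweeps)
library(dplyr)
```

## The scientific question

As a rat runs along a linear track, hippocampal place cells do two
things at once. Each cell fires within a restricted region (its place
field), and within each ~125 ms cycle of the 8 Hz theta oscillation the
population "sweeps" through a short trajectory of represented positions
`r(t)` that starts behind the animal and ends ahead of it. At the
single-cell level the same phenomenon appears as phase precession:
spikes drift to earlier theta phases as the animal crosses the field,
with slope `m` (deg/cm).

How is the sweep coupled to behavior? Three hypotheses are implemented
here as generative models, each a rule mapping the animal's position
`x(t)` and theta phase `theta(t)` to the represented position:

* **spatial sweep** — a fixed spatial look-around:
  `r = x + h * d_theta * (theta - theta0)/360`, with theta distance
  `d_theta` (cm) and heading `h = +-1`;
* **temporal sweep** — a fixed look-ahead in *time*:
  `r = x(t + tau_theta * (theta - theta0)/360)`, with look-ahead time
  `tau_theta` (s), so the sweep's spatial extent is `v * tau_theta`
  and grows with instantaneous speed;
* **behavior-dependent sweep** — a look-ahead scaled by the
  *characteristic* speed of each location:
  `r = x + h * vbar(x) * tau_theta * (theta - theta0)/360`, where
  `vbar(x)` is the location-wise average running speed.

The schemes make different, testable predictions. To first order, the
theta trajectory length is `L = vT + d_theta` (spatial),
`L = (tau_theta + T) v` (temporal) or
`L = vT + vbar(x) tau_theta` (behavior); measured field size is
`s0 + d_theta`, `s0 + v tau_theta` or `s0 + vbar tau_theta`; and the
precession slope is `-360/d_theta`, `-360/(v tau_theta)` or
`-360/(vbar tau_theta)`. The discriminating observation is that pooled
population measures increase with running speed while *individual*
fields do not change with instantaneous speed — a combination only the
behavior-dependent sweep reproduces.

## The synthetic sessions

`generate_session()` simulates a complete session: a corner-to-corner
trajectory, a theta phase series with a cosine-locked LFP, and spikes
from `n_cells` place cells (default 20) with true fields uniformly
spaced along the track. Spiking is an inhomogeneous Bernoulli
approximation of a Poisson process in `dt = 2` ms bins with

```
P = [15 + 0.2 v] * [1 - 0.35 cos(theta)] * exp(-(r - c)^2 / (2 sigma^2)) * dt
```

so the peak rate grows with running speed and firing is suppressed
near the theta cycle boundary. True-field widths are `sigma = 7` cm
for the spatial and temporal schemes (a 15%-threshold width of 27.3
cm) and `max(4, 0.3 * vbar(c) * tau_theta)` for the behavior scheme,
which makes fields crisper where the animal runs slowly.

Defaults that the generative story does not pin down were chosen once,
on the reasoning below, and are not tuned per analysis:

* **track**: 240 cm, 12 runs per direction — a typical free-running
  linear-track session scale;
* **characteristic profile**: an asymmetric inverted U built from two
  half-cosines, 5 cm/s at the corners, 60 cm/s peak displaced toward
  the first half of the run (`asymmetry = 0.25`) — rats accelerate out
  of a reward corner faster than they brake into the next;
* **run-to-run variability**: each run multiplies the profile by a
  lognormal factor with CV 0.15, so instantaneous speeds cluster
  around the characteristic speed;
* **theta**: 8 Hz with per-cycle frequency CV 0.1 (0 for schematic
  validation runs); LFP sampled at 250 Hz;
* **pauses**: 1–3 s uniform at each corner;
* **tracking**: 40 Hz, linear interpolation for position/speed
  lookups.

`schematic_session()` produces the idealized variant used for
closed-form validation: constant speed, jitter-free theta,
`tau_theta = 0.5` s and `sigma = 6` cm.

One modeling choice deserves emphasis: the sweep term carries the
heading sign. The printed spatial/behavior equations do not mention
running direction, but the temporal scheme — which follows the
trajectory itself — sweeps backward on leftward runs, and the
constant-speed equivalence between schemes (`d_theta = v tau_theta`)
only holds if all three do. Clouds, accelerations and skews are
accordingly reported in the travel frame.

## The analysis pipeline

`analyze_session()` re-derives everything from the raw session, never
from generator internals:

1. **Theta**: 3rd-order Butterworth band-pass 4–12 Hz applied
   forward-backward (zero phase), phase from the analytic signal with
   LFP peaks at 0/360 deg, significance against the 97th percentile of
   a time-permuted surrogate, cycles cut at 0-crossings.
2. **Behavior**: central-difference speed smoothed with a 100 ms
   Gaussian, runs as maximal corner-to-corner monotone epochs (corner
   = within 5 cm of an end), characteristic speed per direction in
   4 cm bins discarding sub-10 cm/s samples except within 40 cm of the
   ends.
3. **Fields**: rates in 4 cm bins (counts/occupancy per bin, then a
   6 cm Gaussian; unvisited bins enter as zero — see "Numerical
   choices"), fields around peaks above 2 Hz with at least 25 spikes,
   extent at 15% of peak, edge-cut fields kept only if the rate fell
   below 66% of peak before the edge, an automated proxy for manual
   screening (reject secondary bumps at 50% of peak separated by a 50%
   trough).
4. **Phase precession**: a session-wide phase offset scanned over
   -60..60 deg in 2 deg steps, then wrapped orthogonal-distance
   regression per field on (position, phase) normalized to [0,1]^2,
   with +-1 cycle re-attachment candidates for phases below 0.3/above
   0.7, Nelder-Mead multi-started from the total-least-squares
   solutions of the wrap configurations.
5. **Decoding**: per significant cycle, Poisson posteriors in
   overlapping 90 deg windows at 30 deg steps over a 70 cm window
   centered on the animal, trajectory from the +-5 cm band line search
   followed by probability-weighted regression; `L` = slope times the
   full cycle period, signed by heading. Cycle averages per speed bin
   require more than five cycles.
6. **Comparison**: Kendall associations of pooled size/slope/L with
   speed, Wilcoxon signed-rank on per-field regression slopes,
   `fit_tau_theta()` for the look-ahead time via
   `360/|m| = vbar * tau_theta` through the origin, variance
   partitioning against border distance, and the three-scheme
   `run_model_comparison()` sign matrix.

## Numerical choices

* **Rate maps.** The raw per-bin rate is smoothed, with unvisited bins
  entering as zero. The alternative (smoothing counts and occupancy
  separately and dividing) extrapolates the edge rate a full kernel
  reach (24 cm) into unvisited territory, because both tails shrink at
  the same rate; on speed-restricted maps this inflated field sizes at
  partially sampled bins enough to manufacture a within-field
  size-vs-speed slope under the *spatial* scheme, which is flat by
  construction. Under the adopted convention the 6 cm kernel bridges
  occupancy gaps of up to about three 4-cm bins and no more — which is
  precisely the regime in which the "more than three consecutive
  zero-occupancy bins" incompleteness rule is informative.
* **Per-speed-bin sizes.** The all-speed extent is the reference
  region for spike counts and the sampling index (pairwise-distance
  fraction of bins with >300 ms occupancy, threshold 0.4), but the 15%
  crossings are searched on the full map: the extent boundary *is* the
  all-speed crossing, so a search confined to it almost never finds
  one.
* **Per-speed-bin slopes.** The same sampling-index gate applies to
  the per-bin precession fits. Without it, sub-clouds truncated to the
  well-sampled part of the field carry varying amounts of the
  field-edge "horns" (below), which manufactures slope-vs-speed
  effects even under the spatial scheme.
* **Trajectory band score.** Probability mass within +-5 cm of a
  candidate line is computed from a piecewise-uniform density over the
  4 cm bins. Scoring bins as point masses makes the band capture two
  or three whole bins in alternation, which biased the grid search by
  up to +20% on noiseless ridges.
* **Wrapped-ODR optimization.** Objective tolerance 1e-8, at most 1e4
  evaluations, four starts (no shift, +1 below 0.3, -1 above 0.7,
  both). On all tested clouds the returned optimum matches an
  exhaustive slope-intercept grid.
* **Ties.** The phase-offset scan breaks exact ties toward 0 deg; the
  trajectory grid search keeps the first maximum.

## Known operational biases

These are properties of the measurement procedures themselves on this
generative family, established with brute-force checks; they matter
when comparing pipeline output against closed forms.

* **Precession slopes are shallow-biased on wide clouds.** Spikes from
  the Gaussian tails of the true field enter the measured extent at
  extreme phases, forming near-horizontal "horns" at the cloud's
  corners that pull the orthogonal fit flat. With `sigma = 7` cm and
  `d_theta = 30` cm the global optimum of the wrapped-ODR objective is
  about -10.3 deg/cm against a closed-form -12, and the recovered
  look-ahead time overestimates the generating 0.57 s by roughly
  15–25%. This is not an optimizer failure (grid search agrees) and is
  visible in the generative model's own worked examples, whose printed
  schematic slopes are likewise shallower than the closed forms.
* **Sign, not magnitude, is lost on steep clouds.** A steep cloud
  spans the full normalized phase range, so an ascending line fits the
  wrapped stripe almost as well as the true descending one. Per-bin
  sub-cloud fits at slow bins flip sign unpredictably while |m|
  follows the predicted pattern; the comparison harness therefore
  tests speed effects on the folded slope -|m|.
* **Short decoded trajectories are attenuated.** Posterior columns
  inherit the width of the sweep-broadened tuning curves, so the
  +-5 cm band fit shrinks per-cycle slopes toward zero, by roughly
  5–18% depending on sweep length (within, but near, the 15%
  validation band for most scheme-speed combinations);
  theta-amplitude modulation also compresses the effective phase of
  the extreme windows by a factor 0.966. Trajectories near the
  corners are additionally truncated by the 70 cm decoding window, so
  speed-effect metrics use cycles more than 35 cm from the ends.
* **The phase-offset scan is weakly identified on these clouds.** The
  wrapped orthogonal error is nearly invariant under rigid phase
  rotations, so on synthetic full-span clouds the scan's argmin is
  noise-driven. It is retained because it is part of the analysis
  definition and is harmless (a rotation plus wrap re-attachment
  leaves slopes essentially unchanged).

## What the sign matrix shows

```{r comparison, eval = FALSE}
cmp <- run_model_comparison(seed = 1)
tidy(cmp)
autoplot(cmp)
```

(Not run here; about 8 minutes.) Each scheme's batch is 3 sessions of
20 cells — the per-animal scale of the study conditions. The expected
pattern: the temporal sweep produces pooled increases *and*
within-field increases (individual fields wrongly track instantaneous
speed); the spatial sweep produces flat within-field effects but no
pooled increases; only the behavior-dependent sweep combines pooled
increases in trajectory length, field size and (folded) precession
slope with flat within-field effects. A metric is called flat when
|Kendall tau| < 0.1 or p > 0.05, mirroring qualitative green/red calls
rather than effect sizes.

## What passing tests do and do not show

The generator emulates linear-track running with an inverted-U speed
profile, lognormal run-to-run variability, a quasi-regular theta
rhythm and Poisson spiking. It does not emulate several features of
real recordings: LFP noise and theta harmonics beyond the significance
mask's reach, spike-sorting contamination, non-place or interneuron
activity, phase-precession curvature, field instability over the
session, or 2D behavior projected to 1D. Agreement of the pipeline
with the generative closed forms therefore validates the analysis
machinery and the internal consistency of the three coding schemes; it
does not by itself certify performance on experimental data with these
additional nuisances.

Problem sizes used in the shipped validation: single sessions of 8–12
runs per direction with 10–20 cells for unit-level checks, 100-cell
constant-speed schematics for decoding closed forms, batches of 3
sessions for the sign matrix and the look-ahead-time recovery, and 200
small null replicates for the calibration of the within-field test.

## Limitations

The package analyzes synthetic sessions only; applying the pipeline
to real multi-unit linear-track recordings requires separate
ingestion (spike sorting, unit classification and 2D-to-1D projection
are out of scope). Acceptance-style recovery of generating parameters
inherits the operational biases listed above: the estimators are
internally consistent (the same procedure applied to data and model
yields comparable values) but not unbiased for the underlying
parameters when clouds are wide or trajectories short.
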