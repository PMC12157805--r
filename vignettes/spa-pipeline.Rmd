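---
title: "Methods: weighing-balance SPA from raw signals to activity domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighing-balance SPA from raw signals to activity domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spabalance)
```

## The measurement principle

A rodent cage rests on a rigid plate supported by three load cells in a
triangular layout. Any movement of the housed animals — ambulation,
grooming, rearing, fidgeting — perturbs the force each cell carries, both by
changing the momentary vertical load (accelerations) and by redistributing
the static load across the plate. Spontaneous physical activity (SPA) is
quantified from the time series of those perturbations, not from the weight
level itself. This vignette documents the models, conventions and numerical
choices the package implements, in pipeline order, and ends with what the
synthetic validation does and does not establish.

## Calibration (signal → grams)

Each cell is calibrated independently with known masses placed at its
mounting point, recording the mean signal over a hold of several seconds
(the averaging window is the user's choice when preparing pairs; ~10 s is
typical). `fit_load_cell()` fits mass on signal by ordinary least squares —
mass is the response because the working equation converts signals into
grams. Diagnostics:

* **R²** is reported, never enforced. A warning fires below 0.999
  (configurable): strain-gauge bridges are so linear over a 200 g working
  range that anything visibly below 1 usually means a wiring or mounting
  defect, not statistics.
* **SEE** `= sqrt(Σe² / (n − 2))` in grams, defined for n ≥ 3, estimates the
  mass resolution of a cell. A healthy rig sits well below 1 g.

`convert_to_weight()` applies the three lines and stores the resultant
`w_total = w1 + w2 + w3`. The sum is the physically meaningful quantity: by
static equilibrium the three reactions always add to the applied load, even
when an off-centre load drives one cell negative.

## Raw stream conventions

Loggers write four numeric columns per line: the three cell signals and the
elapsed time in microseconds. Because the upstream format fixes the set of
columns but not their order, the package adopts **signals first, time last**
as its canonical dialect and provides a `time_col` override; whitespace and
commas are both accepted on input, and the canonical writer emits
space-separated text that round-trips byte-identically. Timestamps are
elapsed microseconds from stream start; the absolute anchor (`start_clock`,
default 11:00) comes from configuration because raw files carry no wall
clock. Non-monotonic timestamps are a hard error: a clock that runs
backwards indicates an acquisition fault, and silently reordering would mask
it.

## Outlier filtering and minute binning

Electrical transients produce isolated spikes far outside the plausible
weight range. The filter drops samples farther than `k = 2` sample standard
deviations (n − 1 denominator; per-period counts are small) from the period
mean. Choices made where the procedure was genuinely open:

* **Period**: the calendar minute, by default. The weight signal is
  nonstationary across the day, so local statistics track it; a per-day
  alternative is available (`outlier_period = "day"`).
* **Target**: the resultant weight, with removal propagated to all three
  cells — a spike is an acquisition event, not a per-cell one.
* **Single pass**: bounds are computed once from the full period and not
  re-iterated, so the filter cannot eat the distribution from the tails.
* **Removed points are dropped, not interpolated**; weight changes are then
  formed between surviving neighbours. Differences never span a minute
  boundary.

Minutes are half-open (`[t, t + 60 s)`): a sample exactly on the boundary
starts the later minute. Empty minutes are preserved with zero counts, and
the effective rate `n_samples / 60` is exported for QC — with ±20%
multiplicative interval jitter around 40 Hz, per-minute rates stay within
[32, 48] Hz.

## SWC, MWC and their dispersion

Within a minute of N surviving samples the per-step signal is the modulus of
the weight change. Two cross-cell combinations exist because "summing the
three cells" is ambiguous at the differencing step:

* `per_cell_abs` (default): `|Δw1| + |Δw2| + |Δw3|`. Registers pure
  redistribution — an animal walking across the plate moves weight from one
  cell to another with zero net change — which is precisely ambulation.
* `resultant_first`: `|Δ(w1 + w2 + w3)|`. Blind to redistribution; retained
  as a switch because it has a clean closed form under the simulator and
  isolates net vertical force changes.

`SWC` sums the steps; `MWC` divides by the number of steps. A minute of N
samples has N − 1 differences, and the package divides by that count — an
index-faithful reading of a sum written `n = 1..N` would over-count by one —
preserving the exact identity `swc = mwc × n_diffs` and the motivating
property that duplicating every change (a doubled sampling rate with the
same per-step distribution) doubles SWC but leaves MWC unchanged.

Minutes with fewer than two surviving samples get `swc = mwc = 0` and are
visible through `n_diffs = 0` rather than dropped: the day-minimum baseline
correction below presumes a value for every recorded minute. `SD-WC` is the
sample SD of the (nonnegative) change sequence and `CV-WC = 100·SD/mean`;
CV is reported missing when the mean is zero and excluded from aggregates.
Aggregation of SD-WC/CV-WC to hours or phases is the arithmetic mean of
per-minute values.

## Baseline correction and day summaries

The quietest minute of a day is taken to reflect minimal animal movement, so
its MWC estimates that day's system noise floor (electrical noise, building
vibration) and is subtracted from all of the day's minutes. The corrected
day has minimum exactly 0, unchanged pairwise differences, and preserved
rank order. The **daily SPA value** is the arithmetic mean of corrected
minute MWC over recorded minutes (the mean, not the sum, so days with
slightly different recorded spans stay comparable). **Nadir** and
**acrophase** are the clock minutes of the day's minimum and maximum, ties
resolving to the earliest minute. Across days, cumulative SPA is the
trapezoidal AUC over ordered daily values with one-day spacing, and
`relative_auc()` expresses one group's AUC as a percentage of a reference.

## Domains

Thresholds are the 25th/50th/75th percentiles of the pooled corrected
minute MWC across all days and groups (per-group thresholds would hide
between-group differences in time-in-domain). Percentile interpolation is
linear between closest ranks (recorded in the output metadata; a
nearest-rank switch exists, and the two differ negligibly at thousands of
pooled minutes). Classification is the nested cut

```
SPA <  P25          -> 1 (Very Low)
P25 <= SPA < P50    -> 2 (Low)
P50 <= SPA <= P75   -> 3 (Moderate)
SPA >  P75          -> 4 (High)
```

with the Moderate domain's inclusive upper bound preserved exactly as the
reference rule states it, asymmetric though it is. Baseline correction
precedes threshold computation and classification. Gap and missing minutes
code to 0 and are excluded from thresholds and tallies, so per-window counts
conserve recorded minutes: 60 per complete hour, 600 dark / 720 light per
day under the default schedule. The reference cut points
(11.0, 16.8, 22.4 g) ship as `reference_thresholds()` for classification
without recomputation. Heat maps lay minutes out in recording order
(rows) by day (columns) with one fixed colour per domain.

## The light schedule

The default profile is an inverted 12:12 cycle recorded 22 h/day: dark
(lamps off) 11:00–18:59 and 07:00–08:59, light 19:00–06:59, and a daily
09:00–11:00 gap for husbandry — 600 dark, 720 light, 120 gap minutes per
day. Schedules are validated to be disjoint and to cover the full day, and
phase assignment is a total function of the clock minute.

## The simulator

`simulate_raw()` generates raw streams from a physical model with fully
known latent state, so pipeline correctness can be established by parameter
recovery rather than by inspection.

* **Statics.** A point load at `(x, y)` on the plate distributes to the
  three cells by the barycentric coordinates of the position with respect to
  the cell triangle (equivalently, solving vertical force balance plus two
  moment equations). Loads sum to the applied mass identically; positions
  outside the triangle produce a negative reaction at the far cell. The cell
  coordinates (plate 60 × 47 cm; apex cell centred 23.5 cm across the short
  side, the symmetric pair 49 cm from the opposite edge; ±14.5 cm spread
  about the midline as this package's convention) are configurable.
* **Activity.** Per sampling step, a perturbation magnitude is drawn
  half-normal with the current phase's scale (`sigma_dark`, `sigma_light`),
  plus the day's baseline floor. The perturbation is applied with
  alternating direction about the static mass, which keeps the simulated
  weight bounded while fixing the expected per-step absolute change of the
  resultant in closed form at `bias + sigma·sqrt(2/π)` (the realized step is
  the mean of two consecutive magnitudes, whose expectation is the
  half-normal mean). The pooled load position random-walks inside the cage
  footprint with step length coupled to the same magnitudes
  (`walk_cm_per_g`), so redistribution activity scales with vertical
  activity, as ambulation does.
* **Imperfections.** Inter-sample intervals are `1/rate` times a uniform
  ±`jitter_frac` factor (default ±20%, reproducing the rate fluctuation that
  motivates MWC); isolated spikes of ±`outlier_mag_g` are injected at
  `outlier_rate`; each day draws a baseline noise floor uniform on
  `[0, daily_bias_g]`. The floor is injected on the *change* scale, not as a
  weight offset — a constant added to the weight level cancels in
  differencing and could never be recovered by the day-minimum correction.
* **Defaults as study conditions.** 23 days × 1320 min at 40 Hz with the
  default schedule mirror the recording design; `static_mass_g = 520`
  approximates a polyethylene cage with bedding plus ten young mice;
  `sigma_dark = 25`, `sigma_light = 10` put simulated minute MWC on the
  scale of the published reference thresholds while giving the nocturnal
  contrast its expected direction; `daily_bias_g = 2` keeps the floor small
  relative to activity; `outlier_rate = 5e-5` yields a few spikes per
  hour. These are plausibility choices validated by self-consistency
  (parameter recovery), not against any particular hardware.

Everything is reproducible from the config seed, and the caller's RNG state
is restored afterwards.

## Numerical and degenerate-input choices

* Timestamps are stored as doubles holding exact integer microsecond values
  (22 h exceeds the 32-bit range); the canonical writer prints them with
  `%.0f` and signals at six decimals, which round-trips exactly.
* Empty raw sources are valid empty streams; empty days, < 2 calibration
  pairs, zero signal variance, < 4 threshold values, and a zero reference
  AUC are errors.
* Group SDs in the vectorised minute aggregation are computed from sums and
  squared sums with a nonnegativity clamp against rounding.
* Ties: nadir/acrophase take the earliest minute; classification at a cut
  point follows the nested rule above exactly.

## Validation design, problem sizes, and limitations

The test suite establishes: exact worked values for every closed-form
quantity (schedule and data-volume arithmetic, cage geometry, classification
boundaries, the SWC/MWC identities); agreement of each nontrivial component
with an independent oracle (hand normal equations for calibration, a 3×3
`solve()` for the load distribution at 1000 random positions, sort-and-
interpolate percentiles, brute-force mean/SD for the outlier rule); and
stochastic recovery on simulated data — one full simulated day with a 3:1
dark:light activity contrast recovers a phase-mean MWC ratio within 5% of 3,
and a simulated day with a nonzero noise floor recovers the injected bias
within the quietest minute's own activity (the floor-plus-half-normal mean
brackets it). Domain localization on the same day puts ≥80% of dark minutes
in the upper two domains and ≥80% of light minutes in the lower two. One
day at 40 Hz (~3.2 million samples) is the scale used for the stochastic
checks; smaller blocks exercise the plumbing.

What this does **not** show: the simulator's activity process is the minimal
structure the MWC statistic assumes (independent half-normal perturbation
magnitudes with a position walk), not a biomechanical model of gait, huddling
or group behaviour; one pooled position stands in for ten animals; ADC
quantization, temperature drift and mechanical resonance are not modelled.
Passing recovery tests therefore validates the *pipeline arithmetic and its
conventions*, not the behavioural interpretation of any real recording. The
published reference thresholds ship for convenience, but thresholds are
distribution-specific: recompute them for any new rig, housing density or
species. Chronobiological quantities beyond nadir/acrophase (cosinor fits,
endogenous period) are out of scope, as are inferential statistics — the
package exports tidy tables for external tools instead.
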