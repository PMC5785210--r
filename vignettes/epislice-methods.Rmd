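---
title: "Methods: models, parameters and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epislice)
```

This vignette documents the models behind each analysis stage, the defaults
they ship with, and the numerical conventions that make results exactly
reproducible. Everything here is asserted by the test suite; where a
convention was a genuine design choice, the reasoning is given.

## 1. Calcium-imaging pipeline

### Signal model

A region's fluorescence trace is treated as

$$F(t) = F_0\,[1 + \Delta F/F(t)]\,, \qquad
\Delta F/F(t) = s(t) + d(t) + \varepsilon(t),$$

where $s(t)$ is the seizure-like-event (SLE) signal, $d(t)$ a slow additive
baseline drift (focus, bleaching, indicator expression), and $\varepsilon$
white noise. `compute_dff()` defines $F_0$ as the mean raw fluorescence over
a pre-drug baseline window and errors when $F_0 \le 0$ rather than producing
unusable ratios.

### Baseline correction

`detrend_trace()` subtracts a **rolling lower-percentile baseline**: the
10th percentile over a centered 60-s window, evaluated every
`baseline_stride_s` (1 s) and linearly interpolated back to the frame grid,
then median-centered. A low percentile tracks slow drift while ignoring the
events themselves (SLEs occupy well under half of any window early in the
recording); the stride makes the cost independent of the frame rate — the
window percentile itself is computed in C++ (`nth_element`, matching R's
type-7 quantile) so an 80-minute 10-Hz trace detrends in well under 0.1 s.

### Noise and threshold

`estimate_noise()` is a robust scale estimate designed to ignore the
(strictly positive) event signal: $1.4826 \times$ the median absolute
deviation about the trace median, computed over the samples **below** the
median. On pure Gaussian noise it is calibrated to the true $\sigma$ (the
tests require recovery of $\sigma = 0.01$ within 10%), and it moves by less
than 15% when 10% of samples are contaminated with large events.

Detection then thresholds at $k\,\hat\sigma$ with $k = 4$, merges
supra-threshold epochs separated by gaps **strictly smaller than** 2 s, and
discards events shorter than 1 s. All intervals are half-open $[s, e)$
seconds; merging, clipping, overlap and Jaccard arithmetic live in dedicated
helpers so every downstream quantity reduces to exact interval arithmetic.

### Binning and plateau summary

`time_in_sle()` reports the fraction of each 5-min bin covered by events
(overlap divided by bin width, so
$\sum_b \mathrm{fraction}_b \times \mathrm{width}_b$ equals the total event
time exactly — a conservation law the tests enforce to $10^{-9}$), and the
**plateau percentage**: percent of the 2400–4800 s window covered by events,
computed from the raw intervals rather than the binned values. If the
recording ends before the plateau window does, the percentage is computed
over the overlap and flagged `plateau_truncated`.

### Detection parameters

| parameter | default | meaning |
|---|---|---|
| `baseline_window_s` | 60 | rolling-percentile window |
| `baseline_percentile` | 10 | lower percentile tracked as baseline |
| `baseline_stride_s` | 1 | stride between percentile evaluations |
| `threshold_k` | 4 | threshold in units of robust noise SD |
| `merge_gap_s` | 2 | gaps strictly below this are bridged |
| `min_event_s` | 1 | shorter events are discarded |
| `bin_width_s` | 300 | time-in-SLE bin width |
| `plateau_window` | 2400–4800 s | plateau summary window |

## 2. Synthetic calcium generator

`simulate_dff_trace()` produces a trace **and** the exact event intervals
that generated it, so recovery can be scored without circularity.

- **Event process.** Candidate events are an inhomogeneous Poisson process
  whose rate rises sigmoidally after drug onset (midpoint 1200 s, scale
  240 s, plateau from 2400 s), thinned sequentially so that durations
  (truncated normal, mean 20 s, SD 5 s, minimum 2 s) never overlap and gaps
  are at least 5 s.
- **Occupancy is the dial.** Rather than exposing a raw event rate, the
  generator is parameterized by `plateau_occupancy` $p$: the expected
  fraction of plateau time inside events. With mean duration $d$ and
  minimum gap $g$ the plateau candidate rate is set to
  $1/\lambda = d/p - d - g$, so the programmed occupancy is exact in
  expectation. This is what makes the end-to-end experiment honest: a
  "50% reduction" is programmed as occupancy $0.4 \to 0.2$, not tuned.
- **Within-event signal.** Each event is a dense (8 Hz) train of calcium
  transients with a peak-normalized difference-of-exponentials kernel
  (rise 50 ms, decay 400 ms) and per-transient amplitudes in
  `amp_range` $\times$ `peak_dff`, assembled by causal convolution on the
  frame grid.
- **Nuisance terms.** AR(1) drift (amplitude 0.05, correlation time 300 s),
  exponential bleach (0.1, $\tau$ = 2000 s), white noise (SD 0.02 — event
  SNR 25 at the default peak of 0.5).
- **Determinism.** A config `seed` drives everything through an isolated
  RNG scope (`with_seed`) that restores the caller's `.Random.seed`, so
  simulations are reproducible and composable.

Defaults are the study conditions (80 min at 10 Hz, washout at 10 min,
first SLE no earlier than 2 min later); they are not a tuning surface. The
generator does **not** emulate optics (shot noise, motion, out-of-focus
light), interictal discharges as a separate class, or spatial structure
within an ROI — it generates region-level ΔF/F directly.

## 3. ROI handling

`roi_set()` accepts logical masks or polygons; polygons are rasterized with
the **even-odd rule at pixel centers** $(c + 0.5, r + 0.5)$, matching how
ImageJ-style outlines are usually burned in. ImageJ `.roi` files (rectangle,
polygon, freehand, traced) are parsed directly from the published big-endian
byte layout, `.zip` bundles and a JSON polygon format are supported, and
`extract_roi_traces()` averages each mask over a TIFF stack (or in-memory
array) per frame.

## 4. Voltage-clamp ramps

### Membrane model

The simulated cell is purely resistive:
$I(t) = g_\mathrm{leak}(V - E_\mathrm{leak}) +
g_\mathrm{KATP}(t)\,(V - E_K)$, with
$g_\mathrm{KATP}(t) = g_\infty + (g_0 - g_\infty)e^{-t/\tau}$ frozen within
each sweep (sweeps are 1.5 s, $\tau$ is a minute-scale washdown). Capacitive
transients are deliberately omitted: the analysis fits only the ramp
segment's steady I–V slope, a well-compensated cell is the intended regime,
and omitting $C\,dV/dt$ makes Ohm's-law oracle tests exact. The protocol is
the standard one: hold −70 mV, 100-ms steps to −100 and −120 mV, a 1-s ramp
−120→−60 mV, then back to hold, at 5 kHz.

### Analyses

- `slope_conductance()`: ordinary least squares of I on V over the ramp
  samples with command in −120…−90 mV (the sub-threshold, linear range);
  slope in pA/mV is nS directly. Noiseless recovery is exact to machine
  precision; with 5 pA sample noise the fit stays within 5% (the ramp range
  contains 2500 samples).
- `input_resistance()`: from the mean currents over the final 20 ms of the
  two prepulse steps, $R = 1000 \times 20\,\mathrm{mV}/\Delta I$ in MΩ.
- `washdown_timecourse()`: per-sweep slope conductance normalized to the
  sweep **nearest 180 s** after break-in (tolerance ±30 s; ties resolve to
  the earlier sweep, and the anchor sweep's normalized value is exactly 1 by
  construction). For the exponential generator the whole normalized curve
  equals $(1 + g_0 e^{-t/\tau})/(1 + g_0 e^{-180/\tau})$ (unit leak), which
  the acceptance tests verify to $10^{-4}$.

## 5. Current-clamp steps and F–I curves

The spiking generator is a **leaky integrate-and-fire** cell (capacitance
40 pF, leak 4 nS to −75 mV, threshold −40 mV, reset −65 mV, 2-ms
refractoriness), chosen because its inter-spike interval has a closed form,

$$\mathrm{ISI} = t_\mathrm{ref} +
\tau \ln\!\frac{V_\infty - V_\mathrm{reset}}{V_\infty - V_\mathrm{th}},
\qquad \tau = C/g,$$

giving an independent oracle for spike counts at every step amplitude.
Noiseless sweeps are rendered event-driven from the exact solution (with a
stereotyped 0.4-ms rise to +30 mV and fall overlaid on the trace); with
membrane noise an Euler integration is used instead. An optional
`katp_leak` conductance to $E_K$ = −90 mV hyperpolarizes and shunts the
cell; spike counts are provably non-increasing in it, and the tests check
this across randomized parameter sets.

`count_aps()` counts upward **0-mV crossings** (default; a
$dV/dt \ge 20$ mV/ms rule is provided as an alternative) with a 2-ms
refractory, inside the **half-open** pulse window. Interpolated crossing
times make the boundary convention exact: a spike whose crossing falls at
the pulse edge belongs to whichever side the half-open window says it does,
and the tests pin that behavior rather than fuzzing it. `fi_curve()` maps
strictly increasing step amplitudes (50–200 pA by default) to counts.

## 6. Statistics

The conventions are fixed and minimal: mean ± SEM; boxplots with median,
quartiles, 1.5×IQR whiskers and outliers beyond them; equal-variance
(Student's) two-tailed *t* test (`two_tailed_t()`, Welch behind a flag);
one-way ANOVA (`one_way_anova()`, equal variances) with Bonferroni-adjusted
pairwise *t* tests — adjusted $p = \min(1, p \times n_\mathrm{pairs})$,
verified against brute force in the tests; stars at 0.05 / 0.005 / 0.0005.
Calibration is tested, not assumed: under the null (3 groups × n = 8,
2000 replicates) the ANOVA type-I rate must land in [0.03, 0.07], and
$F = t^2$ must hold for two groups.

## 7. The end-to-end experiment

`run_demo_experiment()` wires everything together: a wild-type group at
plateau occupancy 0.4 and a "knockout" group programmed at 0.2 (a 50%
reduction), n = 8 slices per group, run through simulation → detrending →
detection → binning → plateau → *t* test per region, plus the washdown and
F–I arms on the electrophysiology side. `demo_power()` replicates the
imaging arm (120 replicates by default) and reports the rejection rate at
$\alpha$ = 0.05 and the mean estimated reduction; with the default effect
size the estimated reduction lands within a few points of 50% and power is
essentially 1. Problem sizes (replicate counts, trace counts in the property
tests) were chosen to keep the full suite in the minutes range on one CPU
while leaving the statistical assertions well-powered.

## 8. Reproducibility conventions

- Every generator takes a `seed`; derived seeds are drawn inside an isolated
  RNG scope and are always below $2^{31}-1$.
- Every CLI run writes a JSON provenance record (package version,
  parameters, seed) sufficient to re-run identically; YAML parameter files
  reject unknown keys instead of silently defaulting.
- All file formats are plain text (TSV with `#` metadata headers, BED-like
  event tables, JSON); `scripts/acceptance.R --seed <int> --out <path>`
  recomputes the headline quantities against the installed package.
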