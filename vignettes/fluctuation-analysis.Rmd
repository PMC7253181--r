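---
title: "Resolving Ca2+ puffs inside global signals: the fluctuation-analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving Ca2+ puffs inside global signals: the fluctuation-analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ca2+ puffs are brief (tens to a few hundreds of milliseconds), tightly
localized (a few micrometres) cytosolic Ca2+ transients produced by
stationary clusters of IP3 receptors.  During a large, cell-wide Ca2+
elevation the whole fluorescence image brightens by several-fold, and the
small puff transients riding on that rise become invisible in the raw
movie.  `puffsd` implements a fluctuation analysis that recovers them: puffs
are fast and local, so they leave a signature in the *temporal variance* of
each pixel that survives after the slow global component and the photon shot
noise are removed.

## The temporal SD pipeline

For a movie `F(t, y, x)` in camera counts, `temporal_sd_stack()` computes,
in order:

1. **Black subtraction** — the camera's fixed offset is removed so that
   counts are proportional to detected photons.
2. **Spatial Gaussian blur** — sigma 2 pixels (about 1 um at the default
   0.53 um TIRF pixel), kernel truncated at 4 sigma, reflective borders.
   This suppresses single-pixel shot noise while preserving puff-sized
   (≈1 um) structures.
3. **Temporal Butterworth band-pass, 3–20 Hz** — rejects the slow global
   rise (below ~1 Hz) and the high-frequency shot-noise tail, keeping the
   band where puff transients concentrate their energy.
4. **Running boxcar SD** — for every pixel, the population variance
   (mean of squares minus squared mean) over a moving 20-frame window
   (160 ms at 125 frames/s), followed by a square root.
5. **Shot-noise correction** — shot noise contributes SD proportional to
   the square root of the mean intensity; the pipeline subtracts
   `scale * sqrt(running mean of the blurred movie)`, with the scale
   measured by `calibrate_noise_scale()` (below).  Corrected values are
   *not* clipped at zero: for pure noise they fluctuate about zero, and
   retaining the negative excursions is what makes the corrected trace
   mean-zero rather than positively biased.

The whole-cell puff-activity trace is the mean of the SD stack over a mask
covering the cell (`roi_trace()`).

### Shot-noise calibration

If counts were photons, shot noise would give variance equal to the mean.
Real counts carry a camera gain, and the blur and band-pass remove part of
the noise power, so the proportionality constant must be measured.
`calibrate_noise_scale()` images a uniform sample at several intensities
(or simulates one with `simulate_noise_series()`), passes each stack through
the identical filter chain, and fits the mean filtered variance against the
mean raw intensity.  The slope of that line is the variance contributed per
count of mean intensity; its square root (`scale_c`) is the classical shot
noise scale.

Two practical refinements matter at the precision of our tests:

* **The running-window SD is a biased estimator.**  With a 20-frame window
  of band-limited (hence correlated) noise, the effective number of
  independent samples is small, and `E[sqrt(var)]` falls a few percent below
  `sqrt(E[var])`.  The calibration therefore also regresses the *mean
  running-window SD* against `sqrt(mean intensity)` through the origin
  (`sd_slope`), using exactly the statistic the pipeline corrects, and the
  SD pipelines use this factor.  This makes the correction unbiased by
  construction, without modelling the bias analytically.
* **The calibration has finite precision.**  `sd_slope_se`, the standard
  error of the through-origin fit, is stored with the calibration.  Any
  downstream null test ("is corrected SD zero?") should compare against
  an uncertainty that includes `sd_slope_se * sqrt(intensity)`, because a
  calibration error shifts every corrected mean coherently.  The residual
  nulling error is also intrinsically intensity-dependent at the ~0.2%
  level (the small-sample bias of the SD depends on the Poisson fourth
  cumulant, which scales as 1/intensity), so exact nulling at every
  intensity with one scalar is not achievable — nor needed at the SD
  amplitudes puffs produce.

### Numerical choices

* **Zero-phase filtering** (forward–backward) is the default so that SD
  transients stay aligned in time with the dF/F0 trace they are overlaid
  on; a causal single pass is available (`zero_phase = FALSE`).
* **Filter initial conditions**: each pass starts from the steady state for
  the record's first value, so a constant input produces exactly its DC
  response (zero, for band- and high-pass) with no startup step.
* **Edge handling**: the temporal filters use odd-reflection padding whose
  length is set from the slowest filter pole (`|pole|^p < 1e-6`).  Even so,
  reflected padding is correlated with the record, which measurably inflates
  the running SD within roughly one low-corner period of the record ends.
  Frames within `ceil(fs / band_low)` of either end are therefore flagged
  invalid (`NA`) in SD outputs, alongside the frames whose boxcar window is
  incomplete.  The calibration averages the same guarded statistic.
* **Population variance** (divide by n) is used in the running window, as
  implied by the mean-of-squares-minus-squared-mean formulation.
* **Boundary of the blur**: reflective (mirror-without-repeat), folded as
  many times as the kernel requires, so the strong 8 px blur is usable on
  small test frames.  Border pixels retain slightly more noise variance
  than interior ones; the analytic band-fraction used in the tests accounts
  for this.

## The spatial cross-check

Temporal fluctuations could in principle come from cell-wide flicker rather
than localized events.  `spatial_sd_trace()` band-passes the movie in time,
then spatially band-passes each frame as a difference of Gaussians (2 px
minus 8 px), computes the spatial variance over the cell mask per frame,
takes the square root, subtracts the predicted spatial shot noise
(calibrated by the same variance-vs-mean procedure applied to the
DoG-filtered images), and smooths with the 160 ms boxcar.  On synthetic
puff recordings the spatial and temporal SD traces are nearly
proportional (r > 0.95 in our tests), supporting the interpretation of the
temporal SD as localized activity.  The spatial variance is computed over
the supplied mask; pass an all-`TRUE` mask to use the full field.

## Trace metrics

* `compute_dff0()` — `(F - F0)/F0` with `F0` the mean of a pre-stimulus
  window (default 100 frames), pixel-wise for movies or on ROI-mean traces.
* `sd_vs_dff_scatter()` — pairs each SD sample with the concurrent dF/F0
  during the rising phase (stimulus to dF/F0 argmax), bins at 0.1 dF/F0,
  and reports per-bin mean SD; bins with fewer than 3 samples are dropped
  to avoid single-sample bins.  Per-frame samples are used (no window
  subsampling before binning).
* `puff_activity_integral()` / `activity_ratio()` — trapezoidal integral
  under the SD trace and its ratio to the global peak, with optional
  normalization to a reference response.
* `kinetics()` — 20–80% rise and 80–20% fall times by linear interpolation,
  relative to the pre-stimulus baseline (zero when there are no
  pre-stimulus samples); a monotone tail yields `NA` fall, not an error.

## Release-flux reconstruction

The whole-cell dF/F0 signal is modelled as release minus first-order
removal, `dF/dt = r(t) - k F`.  `fit_exponential_decay()` estimates `k`
from a free-decay segment (default: the final 30% of the post-peak record)
as `A exp(-k t) + C`; the additive offset guards against an imperfect
return to baseline.  `reconstruct_release_rate()` then forms
`r(t) = dF/dt + k F` with central differences after an optional 5-sample
boxcar (raw frame-to-frame differences of a noisy trace would dominate
`r`; use `smoothing_window = 1` for noiseless data).
`cumulative_release()` integrates `r`, also as a percentage of its final
value, and `punctate_fraction_initial()` / `punctate_fraction_total()`
partition release into punctate and diffuse components by comparing mean
release traces with and without puff activity.  The time at which puff
activity has ceased is operationalized by `puff_end_time()` as the first
post-peak time the whole-cell SD falls below 10% of its flurry peak — a
convention, stated as such.  `diffusion_time()` supplies the
`x^2 / (2 d D)` mean-time estimate used when arguing that diffusion is too
fast to explain a slowly accumulating diffuse component.

## The synthetic generator

`simulate_movie()` produces the phenomenology the analysis assumes, with
ground truth:

* a **global rise** that is the solution of `dG/dt = r(t) - k G` with a
  Gaussian release pulse (default sigma 0.5 s, onset 2 s, `k` 0.22 1/s,
  peak normalized to 6.9 dF/F0, the strong-stimulus amplitude regime; the
  defaults give a 20–80% rise of about 0.7 s).  An infinitely
  differentiable waveform is deliberate: a puff-free rise must carry no
  energy into the 3–20 Hz band, as a smoothly graded elevation does not.
  (An earlier draft used `(1-exp(-t/tau)) exp(-k t)`, whose derivative kink
  at onset leaked broadband power through the band-pass and produced a
  spurious SD transient in the puff-free control.)
* **puff sites**: by default 24 stationary sites (the typical number of
  active hot-spot regions monitored per cell), each emitting events with a
  separable kernel — 2-D Gaussian (sigma 1 um) times an exponential
  rise/decay (20 ms / 60 ms, about 150 ms above 10% of peak) — at a local
  peak amplitude of 0.5 dF/F0.  Event times follow an inhomogeneous
  Poisson process whose rate follows an inverted U in the global dF/F0,
  maximal near dF/F0 = 2, so flurries terminate before the global peak;
  this rate law is a test fixture mimicking the observed phenomenology,
  not a biophysical model.
* an **EMCCD camera model**: counts = gain × Poisson(photon rate) + black
  offset + Gaussian read noise (defaults: gain 5 counts/photon, offset
  100, read noise off, baseline 100 photons/frame/pixel at 125 frames/s,
  0.53 um/pixel).  An optional Michaelis-type saturation ceiling on dF/F0
  mimics indicator saturation and is off by default.

What the simulator does **not** emulate: cell morphology (the baseline is
uniform unless a map is supplied), wave propagation, photobleaching, dark
current drift, motion, and any IP3R gating mechanism.  Tests passing on
synthetic data therefore validate the *pipeline arithmetic and statistics*,
not biological conclusions about real recordings.

`simulate_flux_pair()` builds matched control/puff-suppressed dF/F0 trace
pairs through the same removal model, with the punctate pulse scaled so the
missing early release is exactly the requested fraction of the control
release up to the control peak (fractions in [0, 1); a fraction of 1 has no
finite construction with a fixed diffuse component).

All simulators require an explicit seed and are bit-reproducible given one.

## Problem sizes and test design

The packaged tests run the pipeline end-to-end at deliberately desk-sized
conditions: 48 × 48 px fields, 10 s records (1250 frames at 125 frames/s),
noise calibrations with at least 10^6 voxels per intensity level, 100-seed
Monte-Carlo loops for parameter-recovery checks, and explicit-loop oracle
comparisons on 120 × 16 × 16 stacks.  These sizes keep the full suite
around a minute while leaving every statistical bound comfortably
resolvable; the defaults of the generator itself are the study conditions
described above, not scaled-down versions.

## Known limitations

* The shot-noise correction is a single scalar: read noise adds an
  intensity-independent floor that the `sqrt(mean)` term does not model
  (negligible when shot noise dominates, as for the fluorescein-style
  calibration the procedure assumes).
* SD amplitudes are in arbitrary units; no attempt is made to calibrate
  them to Ca2+ concentration or channel flux.
* Puff-site cataloguing (segmentation, per-site event detection on real
  data) is out of scope; `match_events_to_sd()` scores known, injected
  events only.
* For very short records the guard bands plus window edges consume
  2 × ceil(fs/band_low) + window frames; records much shorter than ~1.5 s
  at 125 frames/s cannot be analysed with the default band.
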