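# puffsd — fluctuation analysis of Ca²⁺ imaging movies

`puffsd` resolves localized Ca²⁺ **puffs** — brief (tens to hundreds of ms),
micrometre-scale Ca²⁺ release events from stationary IP₃-receptor clusters —
inside large, cell-wide Ca²⁺ elevations that otherwise obscure them in
fluorescence imaging movies.  It is written for cell physiologists analysing
TIRF or light-sheet recordings of Ca²⁺-indicator-loaded cells, and for anyone
who needs a fully testable reference implementation of running-SD fluctuation
analysis with photon shot-noise correction.

## The method

For a movie *F(t, y, x)* in camera counts, the temporal pipeline computes,
pixel by pixel,

> SD(t) = √ var₍w₎[ BP₍3–20 Hz₎( G₍σ=2 px₎( F − black ) ) ] − c · √ mean₍w₎[ G(F − black) ]

where *G* is a Gaussian blur (σ ≈ 1 µm, truncated at 4σ), *BP* a zero-phase
Butterworth band-pass, var₍w₎/mean₍w₎ are moments over a running 20-frame
(160 ms) boxcar, and *c* is an empirically calibrated shot-noise scale: the
square root of the slope of filtered variance vs. mean intensity measured on
a uniform-intensity (fluorescein-style) series.  Puffs appear as transient SD
hotspots; a smooth global rise — however large — contributes nothing once the
intensity-dependent shot noise is subtracted.  A spatial
difference-of-Gaussians pipeline (`spatial_sd_trace()`) provides an
independent cross-check, and a kinetic module reconstructs the instantaneous
release flux *r(t) = dF/dt + k·F* from whole-cell ΔF/F₀ traces using a fitted
first-order removal constant *k*, partitioning release into *punctate*
(puff-driven) and *diffuse* components.

A ground-truthed simulator (`simulate_movie()`) generates movies with a
smooth global ΔF/F₀ rise, stationary puff sites, and EMCCD camera noise
(gain × Poisson + offset + read noise), so the entire pipeline is verifiable
without any microscope data.

## Worked example

```r
library(puffsd)

## 1. Calibrate the shot-noise scale on a uniform-intensity series
cal_stacks <- simulate_noise_series(levels = c(30, 100, 250, 500, 900),
                                    shape = c(1100, 48, 48), seed = 11)
cal <- calibrate_noise_scale(cal_stacks, filter_params())
cal
#> <noise_calibration> (temporal pipeline, 5 levels)
#>   variance slope 0.02583 / count  (scale_c = 0.16072, r^2 = 1.0000)
#>   running-SD slope 0.15036 per sqrt(count)

## 2. Simulate a ground-truthed recording (global rise + puff flurry)
sim <- simulate_movie(synthetic_config(), seed = 42)

## 3. Temporal SD analysis and whole-cell traces
sds   <- temporal_sd_stack(sim$movie, filter_params(), cal)
mask  <- roi_mask(matrix(TRUE, 48, 48), "whole cell")
sd_tr <- roi_trace(sds, mask)
dff   <- compute_dff0(roi_trace(subtract_black(sim$movie), mask),
                      baseline_frames = 100)
kinetics(dff, t_stimulus = 2)
#> <kinetics> peak 6.96 at t = 4.43 s; rise(20-80%) 0.772 s; fall(80-20%) undefined s

max(sd_tr$values, na.rm = TRUE)      # flurry peak: 15.6 A.U.
sd(sd_tr$values[sd_tr$times < 2],    # pre-stimulus spread: 0.10 A.U.
   na.rm = TRUE)

## 4. Where does puff activity peak relative to the global rise?
sd_vs_dff_scatter(sd_tr, dff, t_start = 2, normalize = TRUE)
#> <binned_scatter> 40 occupied bins over dF/F0 0.00 .. 7.00 (normalized)
#>   argmax bin midpoint: 1.65 dF/F0

## 5. Release-flux decomposition on a control/suppressed pair
pair <- simulate_flux_pair(0.41, k = 0.22)
punctate_fraction_initial(pair$truth$release_control,
                          pair$truth$release_suppressed,
                          pair$truth$t_peak_control)
#> [1] 0.4095
```

Reading the numbers: the simulated global signal reaches 6.96 ΔF/F₀ (6.9
programmed) with a 0.77 s 20–80% rise; the whole-cell corrected SD trace sits
at a spread of 0.10 A.U. before stimulation and spikes to 15.6 A.U. during
the puff flurry — a ~150× excursion that a puff-free control does not show.
The binned scatter places maximal puff activity early in the rise
(ΔF/F₀ ≈ 1.7 here; the generator's event rate peaks at 2), and the flux
decomposition recovers the 41% punctate share built into the synthetic pair.

Real recordings enter through `read_movie()` (multi-page 16-bit TIFF plus
frame interval, pixel size and camera black level) and an ROI mask
(`read_mask()`); outputs are float32 TIFF stacks (`write_stack()`) and CSV
trace tables (`save_traces()`).

## Package layout

| Path | Contents |
| --- | --- |
| `R/movie_io.R` | stacks, masks, traces; TIFF and CSV I/O |
| `R/filtering.R` | blur, Butterworth band/high-pass, running moments |
| `R/fluctuation.R` | noise calibration, temporal SD stack, spatial SD trace, spectra |
| `R/metrics.R` | ΔF/F₀, ROI traces, binned scatter, integrals, kinetics |
| `R/flux.R` | removal fit, release-flux reconstruction, punctate fractions |
| `R/synthetic.R` | ground-truthed movie / trace / noise simulators |
| `vignettes/fluctuation-analysis.Rmd` | the methods, assumptions and design choices |
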