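# The fluctuation pipelines: photon shot-noise calibration, the pixel-wise
# temporal running-SD stack, the spatial difference-of-Gaussians SD trace,
# and power-spectrum diagnostics.
#
# Shot noise has variance proportional to the mean photon flux.  After the
# blur + band-pass chain the proportionality constant is no longer the camera
# gain alone, so it is measured empirically from uniform-intensity series
# (variance-vs-mean regression), and the SD stack is corrected by subtracting
# scale * sqrt(running mean intensity).

#' Calibrate the shot-noise scale from uniform-intensity series
#'
#' Passes each uniform-intensity stack through the same filter chain as the
#' analysis pipeline and regresses the mean filtered variance against the mean
#' (black-subtracted) raw intensity across levels.  The slope is the variance
#' each camera count of mean intensity contributes after filtering;
#' `scale_c = sqrt(slope)`.
#'
#' Because the running-window SD is computed from few, temporally correlated
#' samples, its expectation falls slightly below `sqrt(slope * mean)`
#' (a small-sample effect of the square root).  The calibration therefore also
#' measures the slope of the mean running-window SD against `sqrt(mean)`
#' directly (`sd_slope`, fitted through the origin); the SD pipelines use this
#' empirically determined factor so that pure shot noise is nulled without
#' bias.
#'
#' @param level_stacks list of at least 3 [movie_stack]s at distinct uniform
#'   intensity levels (e.g. from [simulate_noise_series()] or a fluorescein
#'   dilution series).
#' @param params [filter_params] used by the analysis pipeline.
#' @param pipeline `"temporal"` (blur + band-pass, for [temporal_sd_stack()])
#'   or `"spatial"` (band-pass + difference of Gaussians, for
#'   [spatial_sd_trace()]).
#' @param mask optional ROI mask restricting the measured pixels.
#' @param sigma_strong strong blur sigma (px) for the spatial pipeline.
#' @return object of class `noise_calibration` with fields `slope`,
#'   `intercept`, `scale_c`, `sd_slope`, `sd_slope_se` (standard error of
#'   `sd_slope` from the through-origin fit residuals, for propagating the
#'   calibration uncertainty into downstream null tests), `r_squared`,
#'   `n_levels`, `pipeline` and the per-level diagnostics (`means`,
#'   `variances`, `sds`).
#' @export
calibrate_noise_scale <- function(level_stacks, params = filter_params(),
                                  pipeline = c("temporal", "spatial"),
                                  mask = NULL, sigma_strong = 8) {
  pipeline <- match.arg(pipeline)
  if (!is.list(level_stacks) ||
      !all(vapply(level_stacks, inherits, TRUE, "movie_stack")))
    stop("`level_stacks` must be a list of movie_stack objects")
  if (length(level_stacks) < 3)
    stop("need at least 3 intensity levels to calibrate (got ",
         length(level_stacks), ")")
  w <- params$window_frames
  means <- vars <- sds <- numeric(length(level_stacks))
  for (i in seq_along(level_stacks)) {
    st <- subtract_black(level_stacks[[i]])
    msk <- if (is.null(mask)) NULL else check_mask(mask, st)
    sel <- function(fr) if (is.null(msk)) fr else fr[msk]
    d <- dim(st$data)
    means[i] <- if (is.null(msk)) mean(st$data) else {
      mean(apply(st$data, 1, function(fr) mean(fr[msk])))
    }
    guard <- filter_guard_frames(params, 1 / st$frame_interval)
    rows <- guarded_rows(d[1], guard)
    if (pipeline == "temporal") {
      f <- temporal_bandpass(spatial_blur(st, params$spatial_sigma),
                             params$band_low, params$band_high,
                             order = params$butter_order,
                             zero_phase = params$zero_phase)
      m <- f$data; dim(m) <- c(d[1], d[2] * d[3])
      if (!is.null(msk)) m <- m[, as.vector(msk), drop = FALSE]
      mt <- m[rows, , drop = FALSE]
      mu <- colMeans(mt)
      vars[i] <- mean(colMeans(mt * mt) - mu * mu)
      # same running-window statistic as temporal_sd_stack: windows on the
      # full record, averaged over the guarded window centres
      rm_ <- running_moments(m, w)
      sds[i] <- mean(sqrt(rm_$variance[rows, , drop = FALSE]), na.rm = TRUE)
    } else {
      f <- temporal_bandpass(st, params$band_low, params$band_high,
                             order = params$butter_order,
                             zero_phase = params$zero_phase)
      dog <- spatial_blur(f$data, params$spatial_sigma) -
        spatial_blur(f$data, sigma_strong)
      vf <- apply(dog[rows, , , drop = FALSE], 1, function(fr) {
        px <- sel(fr); m1 <- mean(px); mean(px * px) - m1 * m1
      })
      vars[i] <- mean(vf)
      sds[i] <- mean(sqrt(pmax(vf, 0)))
    }
  }
  if (diff(range(means)) == 0)
    stop("intensity levels are degenerate (all means equal)")
  fit <- stats::lm(vars ~ means)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- if (stats::var(vars) == 0) 1 else summary(fit)$r.squared
  sd_slope <- sum(sds * sqrt(means)) / sum(means)   # through-origin LS fit
  resid_sd <- sds - sd_slope * sqrt(means)
  sd_slope_se <- sqrt(sum(resid_sd^2) /
                        max(length(sds) - 1, 1) / sum(means))
  structure(list(slope = slope, intercept = intercept,
                 scale_c = sqrt(max(slope, 0)), sd_slope = sd_slope,
                 sd_slope_se = sd_slope_se,
                 r_squared = r2, n_levels = length(level_stacks),
                 pipeline = pipeline, window_frames = w,
                 means = means, variances = vars, sds = sds),
            class = "noise_calibration")
}

#' @export
print.noise_calibration <- function(x, ...) {
  cat(sprintf("<noise_calibration> (%s pipeline, %d levels)\n", x$pipeline,
              x$n_levels))
  cat(sprintf("  variance slope %.5g / count  (scale_c = %.5g, r^2 = %.4f)\n",
              x$slope, x$scale_c, x$r_squared))
  cat(sprintf("  running-SD slope %.5g per sqrt(count)\n", x$sd_slope))
  invisible(x)
}

#' @export
coef.noise_calibration <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept,
    scale_c = object$scale_c, sd_slope = object$sd_slope)
}

#' Save / load a noise calibration as JSON
#' @param calibration a `noise_calibration`.
#' @param path JSON file path.
#' @return the calibration (read) or `path` invisibly (write).
#' @export
write_calibration <- function(calibration, path) {
  jsonlite::write_json(unclass(calibration), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "noise_calibration")
}

# Frames within one period of the low band edge of either record end carry
# the zero-phase filter's startup transient (measurably inflated variance on
# pure noise) and are excluded from SD statistics.
filter_guard_frames <- function(params, fs) {
  as.integer(ceiling(fs / params$band_low))
}

# row indices of a T-long record that are outside the guard bands
guarded_rows <- function(T_, guard) {
  if (2 * guard >= T_) stop("record too short for the filter guard bands (",
                            T_, " frames, guard ", guard, ")")
  seq.int(guard + 1L, T_ - guard)
}

# scale used for the sqrt(mean) correction term
correction_scale <- function(calibration) {
  if (is.null(calibration)) return(0)
  if (!is.null(calibration$sd_slope)) calibration$sd_slope
  else calibration$scale_c
}

#' Temporal running-SD stack
#'
#' The core fluctuation analysis.  Starting from the black-subtracted movie:
#' spatial Gaussian blur (sigma `params$spatial_sigma`), temporal Butterworth
#' band-pass (`band_low`--`band_high` Hz), then for every pixel the running
#' population SD over a `window_frames` boxcar; finally the predicted photon
#' shot noise, `scale * sqrt(running mean of the blurred movie)`, is
#' subtracted pixel-by-pixel.  Negative corrected values are retained (they
#' are noise about zero); frames whose window is incomplete are `NA`.
#'
#' @param movie a [movie_stack] (black level taken from its metadata).
#' @param params [filter_params].
#' @param calibration a `noise_calibration` from [calibrate_noise_scale()]
#'   (temporal pipeline), or `NULL` for the uncorrected SD stack.
#' @return object of class `sd_stack`: `data` (T x Y x X corrected SD, `NA`
#'   at invalid edges), plus the movie metadata, `params` and `window_frames`.
#' @export
temporal_sd_stack <- function(movie, params = filter_params(),
                              calibration = NULL) {
  if (!inherits(movie, "movie_stack")) stop("`movie` must be a movie_stack")
  w <- params$window_frames
  T_ <- dim(movie$data)[1]
  if (T_ < w) stop("movie shorter (", T_, " frames) than the SD window (",
                   w, ")")
  if (!is.null(calibration) && !is.null(calibration$pipeline) &&
      calibration$pipeline != "temporal")
    stop("calibration was made for the '", calibration$pipeline,
         "' pipeline; temporal_sd_stack needs a temporal calibration")
  bs <- subtract_black(movie)
  g <- spatial_blur(bs, params$spatial_sigma)
  f <- temporal_bandpass(g, params$band_low, params$band_high,
                         order = params$butter_order,
                         zero_phase = params$zero_phase)
  vr <- running_moments(f, w)$variance
  sd_raw <- sqrt(vr)
  mn <- running_moments(g, w)$mean
  corr <- correction_scale(calibration) * sqrt(pmax(mn, 0))
  out <- sd_raw - corr
  guard <- filter_guard_frames(params, 1 / movie$frame_interval)
  valid <- guarded_rows(T_, guard)
  out[setdiff(seq_len(T_), valid), , ] <- NA_real_
  structure(list(data = out,
                 window_frames = w,
                 params = params,
                 corrected = !is.null(calibration),
                 frame_interval = movie$frame_interval,
                 pixel_size = movie$pixel_size,
                 black_level = 0,
                 t0_stimulus = movie$t0_stimulus),
            class = "sd_stack")
}

#' @export
print.sd_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sd_stack> %d frames of %d x %d px (window %d frames = %.0f ms)%s\n",
              d[1], d[2], d[3], x$window_frames,
              x$window_frames * x$frame_interval * 1000,
              if (isTRUE(x$corrected)) ", shot-noise corrected" else
                ", uncorrected"))
  invisible(x)
}

#' @export
dim.sd_stack <- function(x) dim(x$data)

#' Spatial-fluctuation SD trace
#'
#' Cross-check pipeline: the black-subtracted movie is temporally band-passed
#' with the same band as the temporal pipeline, each frame is spatially
#' band-passed as the difference of weak (`params$spatial_sigma`, default
#' 2 px) and strong (`sigma_strong`, default 8 px) Gaussian blurs, and the
#' spatial variance over the masked pixels is taken per frame.  Its square
#' root, minus the predicted spatial shot noise
#' `scale * sqrt(mean masked intensity)`, is boxcar-averaged over
#' `window_frames` to give the whole-cell spatial SD trace.
#'
#' @param movie a [movie_stack].
#' @param cell_mask ROI mask (use an all-`TRUE` mask for the full field).
#' @param params [filter_params].
#' @param calibration a spatial-pipeline `noise_calibration`, or `NULL` for
#'   no shot-noise subtraction.
#' @param sigma_strong strong blur sigma in pixels.
#' @return a [puff_trace] (units `"SD (A.U.)"`, `NA` at boxcar edges).
#' @export
spatial_sd_trace <- function(movie, cell_mask, params = filter_params(),
                             calibration = NULL, sigma_strong = 8) {
  if (!inherits(movie, "movie_stack")) stop("`movie` must be a movie_stack")
  msk <- check_mask(cell_mask, movie)
  if (!is.null(calibration) && !is.null(calibration$pipeline) &&
      calibration$pipeline != "spatial")
    stop("calibration was made for the '", calibration$pipeline,
         "' pipeline; spatial_sd_trace needs a spatial calibration")
  bs <- subtract_black(movie)
  f <- temporal_bandpass(bs, params$band_low, params$band_high,
                         order = params$butter_order,
                         zero_phase = params$zero_phase)
  dog <- spatial_blur(f$data, params$spatial_sigma) -
    spatial_blur(f$data, sigma_strong)
  sel <- as.vector(msk)
  d <- dim(dog); dim(dog) <- c(d[1], d[2] * d[3])
  dog <- dog[, sel, drop = FALSE]
  mu <- rowMeans(dog)
  vf <- rowMeans(dog * dog) - mu * mu
  raw <- bs$data; dim(raw) <- c(d[1], d[2] * d[3])
  mean_int <- rowMeans(raw[, sel, drop = FALSE])
  sd_tr <- sqrt(pmax(vf, 0)) -
    correction_scale(calibration) * sqrt(pmax(mean_int, 0))
  guard <- filter_guard_frames(params, 1 / movie$frame_interval)
  valid <- guarded_rows(d[1], guard)
  smoothed <- rep(NA_real_, d[1])
  smoothed[valid] <- running_moments(sd_tr[valid],
                                     params$window_frames)$mean
  puff_trace(frame_times(movie), smoothed, "SD (A.U.)")
}

#' Match known events against SD-stack hotspots
#'
#' For each event in a ground-truth table (e.g. from [simulate_movie()]),
#' looks for the SD maximum in the frames within `frame_tol` of the event
#' peak time and scores a hit when that maximum lies within `space_tol_px`
#' pixels of the event's site.  Events whose search window contains no valid
#' SD frame (edge/guard frames) are excluded from the recall denominator.
#'
#' @param sd_stack an [temporal_sd_stack()] result.
#' @param events data frame with columns `y`, `x` and `t_peak_s` (or
#'   `onset_s`).
#' @param space_tol_px spatial tolerance in pixels (default 1).
#' @param frame_tol temporal tolerance in frames (default half the SD
#'   window).
#' @return list: `hits` (logical per scored event), `recall`, `n_scored`,
#'   `n_excluded`, and the per-event offsets `dy`, `dx`, `dframe`.
#' @export
match_events_to_sd <- function(sd_stack, events, space_tol_px = 1,
                               frame_tol = NULL) {
  if (is.null(frame_tol)) frame_tol <- sd_stack$window_frames / 2
  dt <- sd_stack$frame_interval
  tp <- if (!is.null(events$t_peak_s)) events$t_peak_s else events$onset_s
  T_ <- dim(sd_stack$data)[1]
  hits <- logical(0); dys <- dxs <- dfs <- integer(0)
  n_excluded <- 0L
  for (i in seq_len(nrow(events))) {
    fr <- 1L + round(tp[i] / dt)
    win <- max(1L, fr - frame_tol):min(T_, fr + frame_tol)
    sub <- sd_stack$data[win, , , drop = FALSE]
    if (all(is.na(sub))) { n_excluded <- n_excluded + 1L; next }
    am <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
    dys <- c(dys, am[2] - events$y[i])
    dxs <- c(dxs, am[3] - events$x[i])
    dfs <- c(dfs, win[am[1]] - fr)
    hits <- c(hits, abs(am[2] - events$y[i]) <= space_tol_px &&
                abs(am[3] - events$x[i]) <= space_tol_px)
  }
  list(hits = hits, recall = if (length(hits)) mean(hits) else NA_real_,
       n_scored = length(hits), n_excluded = n_excluded,
       dy = dys, dx = dxs, dframe = dfs)
}

#' Averaged power spectrum of fluorescence traces
#'
#' Each trace is high-pass filtered (default 1 Hz corner, zero phase) to strip
#' the slow global rise, mean-detrended, Hann-tapered and periodogram-ed; the
#' one-sided spectra are averaged across traces.  Each spectrum is normalized
#' so that the total power times the bin width equals the variance of the
#' filtered, detrended trace (Parseval).
#'
#' @param traces list of [puff_trace]s, a T x N matrix, or a numeric vector
#'   (>= 64 samples each, equal lengths).
#' @param fs sampling rate in Hz (taken from the traces when omitted).
#' @param highpass_cutoff pre-filter corner in Hz; `0` disables it.
#' @param order high-pass filter order.
#' @return object of class `power_spectrum` with fields `frequencies` (Hz),
#'   `power` (A.U.^2/Hz), `df` and `n_averaged`.
#' @export
power_spectrum <- function(traces, fs = NULL, highpass_cutoff = 1,
                           order = 2) {
  if (inherits(traces, "puff_trace")) traces <- list(traces)
  if (is.list(traces)) {
    if (!length(traces)) stop("need at least one trace")
    if (is.null(fs)) fs <- 1 / trace_dt(traces[[1]])
    mat <- vapply(traces, function(tr) {
      if (inherits(tr, "puff_trace")) tr$values else as.numeric(tr)
    }, numeric(length(if (inherits(traces[[1]], "puff_trace"))
      traces[[1]]$values else traces[[1]])))
    if (is.null(dim(mat))) mat <- matrix(mat, ncol = length(traces))
  } else if (is.matrix(traces)) {
    mat <- traces
  } else {
    mat <- matrix(as.numeric(traces), ncol = 1)
  }
  if (is.null(fs)) stop("`fs` must be supplied for plain matrices/vectors")
  n <- nrow(mat)
  if (n < 64) stop("traces must have at least 64 samples (got ", n, ")")
  if (highpass_cutoff > 0)
    mat <- temporal_highpass(mat, highpass_cutoff, fs = fs, order = order)
  taper <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))  # Hann
  nf <- n %/% 2
  df <- fs / n
  freqs <- seq_len(nf) * df
  acc <- numeric(nf)
  for (j in seq_len(ncol(mat))) {
    xd <- mat[, j] - mean(mat[, j])
    v <- mean(xd * xd)
    X <- stats::fft(xd * taper)
    p <- Mod(X[1 + seq_len(nf)])^2
    tot <- sum(p) * df
    if (tot > 0) p <- p * (v / tot)   # Parseval normalization
    acc <- acc + p
  }
  structure(list(frequencies = freqs, power = acc / ncol(mat), df = df,
                 fs = fs, n_averaged = ncol(mat),
                 highpass_cutoff = highpass_cutoff),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins up to %.3g Hz, averaged over %d trace(s)\n",
              length(x$frequencies), max(x$frequencies), x$n_averaged))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, ..., log = "xy",
                                xlab = "frequency (Hz)",
                                ylab = "power (A.U.²/Hz)") {
  graphics::plot(x$frequencies, x$power, type = "l", log = log,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Integrated spectral power in a frequency band
#'
#' @param spectrum a `power_spectrum`.
#' @param f_low,f_high band edges in Hz (inclusive).
#' @return total power in the band (A.U.^2).
#' @export
band_power <- function(spectrum, f_low, f_high) {
  sel <- spectrum$frequencies >= f_low & spectrum$frequencies <= f_high
  if (!any(sel)) stop("no spectral bins inside [", f_low, ", ", f_high, "] Hz")
  sum(spectrum$power[sel]) * spectrum$df
}
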