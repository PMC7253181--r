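# Kinetic decomposition of whole-cell Ca2+ signals.
#
# The cytosolic fluorescence F (dF/F0) is modelled as a balance between
# release into the cytosol and first-order removal:  dF/dt = r(t) - k F.
# Fitting k from a free-decay segment lets the instantaneous release flux be
# reconstructed as r(t) = dF/dt + k F, and its running integral gives the
# cumulative release.  Comparing mean release traces with and without puff
# activity partitions release into punctate and diffuse components.

#' Fit a single-exponential decay
#'
#' Nonlinear least squares of `A * exp(-k * t) + C` to a decaying trace
#' segment, e.g. the tail of a global Ca2+ signal after release has ceased.
#' Time is measured from the start of the fit window.
#'
#' @param trace a [puff_trace].
#' @param window `c(t0, t1)` fit window in seconds; default the final 30% of
#'   the record after the trace maximum (the decay tail).
#' @return object of class `removal_fit`: `k` (1/s), `amplitude`, `offset`,
#'   `fit_window`, `residual_rmse` and the underlying `nls` fit.
#' @export
fit_exponential_decay <- function(trace, window = NULL) {
  ok <- is.finite(trace$values)
  tt <- trace$times[ok]; vv <- trace$values[ok]
  if (is.null(window)) {
    ip <- which.max(vv)
    t_end <- tt[length(tt)]
    window <- c(t_end - 0.3 * (t_end - tt[ip]), t_end)
  }
  if (window[1] < tt[1] - 1e-9 || window[2] > tt[length(tt)] + 1e-9 ||
      window[1] >= window[2])
    stop("fit window outside the record")
  sel <- tt >= window[1] & tt <= window[2]
  if (sum(sel) < 4) stop("fewer than 4 samples in the fit window")
  ts <- tt[sel] - window[1]
  ys <- vv[sel]
  sl <- stats::coef(stats::lm(ys ~ ts))[2]
  if (sl >= 0) stop("trace is not decreasing on average over the fit window")
  C0 <- min(ys)
  A0 <- max(ys[1] - C0, 1e-8)
  # crude initial rate from the log-linear drop across the window
  drop <- (ys[1] - C0 + 1e-8) / (ys[length(ys)] - C0 + 1e-8)
  k0 <- max(log(max(drop, 1.01)) / (ts[length(ts)] - ts[1]), 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(ys ~ A * exp(-k * ts) + C,
                      start = list(A = A0, k = k0, C = C0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("exponential fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  if (cf[["k"]] <= 0) stop("fitted rate constant k <= 0")
  structure(list(k = unname(cf[["k"]]), amplitude = unname(cf[["A"]]),
                 offset = unname(cf[["C"]]), fit_window = window,
                 residual_rmse = sqrt(mean(stats::residuals(fit)^2)),
                 fit = fit),
            class = "removal_fit")
}

#' @export
print.removal_fit <- function(x, ...) {
  cat(sprintf("<removal_fit> k = %.4g 1/s over [%.3g, %.3g] s (A = %.3g, C = %.3g, RMSE %.3g)\n",
              x$k, x$fit_window[1], x$fit_window[2], x$amplitude, x$offset,
              x$residual_rmse))
  invisible(x)
}

#' @export
coef.removal_fit <- function(object, ...) {
  c(k = object$k, amplitude = object$amplitude, offset = object$offset)
}

# centered boxcar smoothing with shrinking windows at the edges
boxcar_smooth <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  h <- (w - 1) %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + (w - 1 - h), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Reconstruct the instantaneous release flux
#'
#' `r(t) = dF/dt + k F(t)`: the time derivative of the whole-cell dF/F0
#' signal plus the estimated removal.  The derivative uses central
#' differences (one-sided at the ends) after optional boxcar smoothing of the
#' trace; for noiseless traces set `smoothing_window = 1`.
#'
#' @param dff_trace uniformly sampled whole-cell dF/F0 [puff_trace].
#' @param k removal rate constant (1/s, > 0).
#' @param smoothing_window boxcar length in samples applied before
#'   differentiation (default 5).
#' @return a [puff_trace] of the release rate (dF/F0 per s).
#' @export
reconstruct_release_rate <- function(dff_trace, k, smoothing_window = 5) {
  if (k <= 0) stop("`k` must be > 0")
  n <- length(dff_trace$values)
  if (n < 3) stop("need at least 3 samples")
  dt <- trace_dt(dff_trace)
  f <- boxcar_smooth(dff_trace$values, as.integer(smoothing_window))
  dfdt <- numeric(n)
  dfdt[1] <- (f[2] - f[1]) / dt
  dfdt[n] <- (f[n] - f[n - 1]) / dt
  dfdt[2:(n - 1)] <- (f[3:n] - f[1:(n - 2)]) / (2 * dt)
  puff_trace(dff_trace$times, dfdt + k * f, "dF/F0 per s")
}

#' Cumulative release
#'
#' Running trapezoidal integral of the release-rate trace, also expressed as
#' a percentage of its final value.
#'
#' @param release_trace a uniformly sampled release-rate [puff_trace].
#' @return object of class `cumulative_release`: traces `cumulative` (dF/F0)
#'   and `percent` (% of final value).
#' @export
cumulative_release <- function(release_trace) {
  tt <- release_trace$times; vv <- release_trace$values
  n <- length(vv)
  inc <- c(0, diff(tt) * (vv[-n] + vv[-1]) / 2)
  cum <- cumsum(inc)
  final <- cum[n]
  pct <- if (final != 0) 100 * cum / final else rep(0, n)
  structure(list(cumulative = puff_trace(tt, cum, "dF/F0"),
                 percent = puff_trace(tt, pct, "% of final"),
                 final = final),
            class = "cumulative_release")
}

#' @export
print.cumulative_release <- function(x, ...) {
  cat(sprintf("<cumulative_release> final %.4g dF/F0 over %.3g s\n",
              x$final, diff(range(x$cumulative$times))))
  invisible(x)
}

#' Punctate fraction of the initial release
#'
#' Compares mean release traces from cells with normal puff activity
#' (control) and with puffs suppressed: the fraction of the control release
#' up to `t_end` (the time of the peak of the global signal) that is missing
#' when puffs are absent,
#' `(int control - int suppressed) / int control`, clipped to \[0, 1\].
#'
#' @param release_control,release_suppressed release-rate [puff_trace]s on a
#'   common time base.
#' @param t_end end of the initial-rise window (s).
#' @return scalar fraction in \[0, 1\].
#' @export
punctate_fraction_initial <- function(release_control, release_suppressed,
                                      t_end) {
  t0 <- max(min(release_control$times), min(release_suppressed$times))
  ic <- puff_activity_integral(release_control, t0, t_end)
  is_ <- puff_activity_integral(release_suppressed, t0, t_end)
  if (ic <= 0) stop("control release integral is not positive")
  min(max((ic - is_) / ic, 0), 1)
}

#' Punctate percentage of the total release
#'
#' Given the cumulative release expressed as a percentage of its final value,
#' the overall punctate share is
#' `initial_fraction * cumulative%(t_puff_end)`, taking all punctate release
#' to have occurred by the time puff activity ceased.
#'
#' @param cumulative a `cumulative_release` object, or a percent
#'   [puff_trace].
#' @param t_puff_end time at which puff activity has ceased (s), e.g. from
#'   [puff_end_time()].
#' @param initial_fraction punctate fraction of the initial release
#'   (\[0, 1\]).
#' @return percentage of the total release attributable to puffs.
#' @export
punctate_fraction_total <- function(cumulative, t_puff_end,
                                    initial_fraction) {
  pct <- if (inherits(cumulative, "cumulative_release")) cumulative$percent
         else cumulative
  if (!(initial_fraction >= 0 && initial_fraction <= 1))
    stop("`initial_fraction` must be in [0, 1]")
  if (t_puff_end < min(pct$times) || t_puff_end > max(pct$times))
    stop("`t_puff_end` outside the record")
  initial_fraction * interp_trace(pct, t_puff_end)
}

#' Mean diffusion time over a distance
#'
#' `t = x^2 / (2 * dims * D)` for Brownian motion in `dims` dimensions: the
#' mean time for an ion with effective diffusion coefficient `D` to cover a
#' distance `x` (e.g. ~0.31 s for 5 um at 20 um^2/s in 2-D).
#'
#' @param distance_um distance in micrometres (>= 0).
#' @param D_um2_per_s effective diffusion coefficient (um^2/s, > 0).
#' @param dims dimensionality (1, 2 or 3).
#' @return time in seconds.
#' @export
diffusion_time <- function(distance_um, D_um2_per_s, dims = 2) {
  if (!dims %in% c(1, 2, 3)) stop("`dims` must be 1, 2 or 3")
  if (any(distance_um < 0)) stop("`distance_um` must be >= 0")
  if (D_um2_per_s <= 0) stop("`D_um2_per_s` must be > 0")
  distance_um^2 / (2 * dims * D_um2_per_s)
}
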