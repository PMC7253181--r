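# Derived measurements: dF/F0 normalization, ROI traces, the binned
# SD-vs-dF/F0 scatter, activity integrals and rise/fall kinetics.

#' Compute dF/F0
#'
#' `(F - F0) / F0`, where `F0` is the mean over a pre-stimulus baseline
#' window.  For movies the normalization is pixel-wise; for traces it acts on
#' the trace values.
#'
#' @param x a [movie_stack] or [puff_trace].
#' @param baseline_frames either a single count `n` (the first `n` frames; if
#'   the stack carries `t0_stimulus`, the `n` frames immediately before it) or
#'   an explicit vector of frame indices.  Default 100 frames.
#' @param eps positive floor for `F0`: an error is raised wherever the
#'   baseline mean does not exceed it.
#' @return same type as `x`, values in dF/F0 units.
#' @export
compute_dff0 <- function(x, baseline_frames = 100, eps = 1e-6) {
  resolve_baseline <- function(T_, t0) {
    if (length(baseline_frames) == 1L) {
      n <- as.integer(baseline_frames)
      if (n < 1) stop("baseline window is empty")
      if (!is.null(t0)) {
        idx <- seq_len(t0 - 1L)
        idx <- utils::tail(idx, n)
      } else idx <- seq_len(min(n, T_))
    } else idx <- as.integer(baseline_frames)
    if (!length(idx) || any(idx < 1L) || any(idx > T_))
      stop("baseline window is empty or outside the record")
    idx
  }
  if (inherits(x, "movie_stack")) {
    bs <- subtract_black(x)
    T_ <- dim(bs$data)[1]
    idx <- resolve_baseline(T_, x$t0_stimulus)
    f0 <- apply(bs$data[idx, , , drop = FALSE], c(2, 3), mean)
    if (any(f0 <= eps))
      stop("baseline F0 <= eps at ", sum(f0 <= eps),
           " pixel(s); mask the field or raise the baseline")
    out <- bs
    out$data <- sweep(sweep(bs$data, c(2, 3), f0, "-"), c(2, 3), f0, "/")
    return(out)
  }
  if (inherits(x, "puff_trace")) {
    T_ <- length(x$values)
    idx <- resolve_baseline(T_, NULL)
    f0 <- mean(x$values[idx])
    if (f0 <= eps) stop("baseline F0 <= eps")
    return(puff_trace(x$times, (x$values - f0) / f0, "dF/F0"))
  }
  stop("`x` must be a movie_stack or puff_trace")
}

#' Mean trace over an ROI
#'
#' Per-frame mean of the masked pixels, as a time trace.
#'
#' @param stack a [movie_stack] or [sd_stack].
#' @param roi ROI mask (logical Y x X).
#' @param units unit label for the resulting trace.
#' @return a [puff_trace].
#' @export
roi_trace <- function(stack, roi,
                      units = if (inherits(stack, "sd_stack")) "SD (A.U.)"
                              else "F (counts)") {
  msk <- check_mask(roi, stack)
  d <- dim(stack$data)
  m <- stack$data; dim(m) <- c(d[1], d[2] * d[3])
  vals <- rowMeans(m[, as.vector(msk), drop = FALSE])
  puff_trace((seq_len(d[1]) - 1) * stack$frame_interval, vals, units)
}

#' Binned SD-vs-dF/F0 scatter over the rising phase
#'
#' Pairs each SD sample with the concurrent dF/F0 value over the rising phase
#' `[t_start, t_peak]` of the global signal, bins by dF/F0 (default width
#' 0.1), and reports the per-bin mean SD.  Bins with fewer than `min_count`
#' samples are reported as `NA`.
#'
#' @param sd_trace,dff_trace [puff_trace]s on a common time base.
#' @param t_start start of the rising phase (s), e.g. the stimulus time.
#' @param t_peak end of the rising phase (s); defaults to the time of the
#'   dF/F0 maximum after `t_start`.
#' @param bin_width dF/F0 bin width.
#' @param normalize divide the per-bin means by their maximum.
#' @param min_count minimum samples per reported bin.
#' @return object of class `binned_scatter`: `bin_edges`, `bin_mid`,
#'   `mean_sd`, `counts`, `normalized`.
#' @export
sd_vs_dff_scatter <- function(sd_trace, dff_trace, t_start, t_peak = NULL,
                              bin_width = 0.1, normalize = FALSE,
                              min_count = 3) {
  if (length(sd_trace$times) != length(dff_trace$times) ||
      max(abs(sd_trace$times - dff_trace$times)) > 1e-9)
    stop("SD and dF/F0 traces must share a time base")
  if (is.null(t_peak)) {
    post <- dff_trace$times >= t_start
    if (!any(post)) stop("no samples after t_start")
    t_peak <- dff_trace$times[post][which.max(dff_trace$values[post])]
  }
  if (!(t_start < t_peak)) stop("need t_start < t_peak")
  sel <- sd_trace$times >= t_start & sd_trace$times <= t_peak &
    is.finite(sd_trace$values) & is.finite(dff_trace$values)
  if (!any(sel)) stop("no samples in the rising-phase window")
  sdv <- sd_trace$values[sel]
  dff <- dff_trace$values[sel]
  lo <- floor(min(dff) / bin_width) * bin_width
  hi <- ceiling(max(dff) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  bin <- findInterval(dff, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  counts <- tabulate(bin, nbins = nb)
  mean_sd <- rep(NA_real_, nb)
  for (b in which(counts > 0)) mean_sd[b] <- mean(sdv[bin == b])
  mean_sd[counts < min_count] <- NA_real_
  if (normalize) {
    mx <- max(mean_sd, na.rm = TRUE)
    if (is.finite(mx) && mx != 0) mean_sd <- mean_sd / mx
  }
  structure(list(bin_edges = edges, bin_mid = edges[-length(edges)] +
                   bin_width / 2,
                 mean_sd = mean_sd, counts = counts,
                 normalized = isTRUE(normalize),
                 t_start = t_start, t_peak = t_peak),
            class = "binned_scatter")
}

#' @export
print.binned_scatter <- function(x, ...) {
  occ <- which(!is.na(x$mean_sd))
  cat(sprintf("<binned_scatter> %d occupied bins over dF/F0 %.2f .. %.2f%s\n",
              length(occ), x$bin_edges[1], x$bin_edges[length(x$bin_edges)],
              if (x$normalized) " (normalized)" else ""))
  if (length(occ))
    cat(sprintf("  argmax bin midpoint: %.2f dF/F0\n",
                x$bin_mid[occ[which.max(x$mean_sd[occ])]]))
  invisible(x)
}

#' @export
plot.binned_scatter <- function(x, ..., xlab = expression(Delta * F / F[0]),
                                ylab = if (x$normalized) "SD (norm.)"
                                       else "SD (A.U.)") {
  graphics::plot(x$bin_mid, x$mean_sd, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# linear interpolation of a trace at time t (must be inside the record)
interp_trace <- function(trace, t) {
  stats::approx(trace$times, trace$values, xout = t, rule = 1)$y
}

#' Integral under an SD trace (puff activity)
#'
#' Trapezoidal integral of the trace over `[t0, t1]`, endpoints included by
#' linear interpolation.  Negative excursions are integrated as-is; `NA`
#' samples (invalid SD edge frames) are dropped.
#'
#' @param sd_trace a [puff_trace].
#' @param t0,t1 integration window (s), inside the record.
#' @return scalar integral (trace units x s).
#' @export
puff_activity_integral <- function(sd_trace, t0, t1) {
  ok <- is.finite(sd_trace$values)
  tt <- sd_trace$times[ok]; vv <- sd_trace$values[ok]
  if (!(t0 < t1)) stop("need t0 < t1")
  if (t0 < min(tt) - 1e-9 || t1 > max(tt) + 1e-9)
    stop("integration window [", t0, ", ", t1, "] outside the record")
  t0 <- max(t0, min(tt)); t1 <- min(t1, max(tt))
  inside <- tt > t0 & tt < t1
  xs <- c(t0, tt[inside], t1)
  ys <- c(stats::approx(tt, vv, t0)$y, vv[inside], stats::approx(tt, vv, t1)$y)
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Ratio of puff activity to global signal size
#'
#' @param sd_integral integral under the SD trace (from
#'   [puff_activity_integral()]).
#' @param peak_dff0 peak of the global dF/F0 signal (> 0).
#' @param ref_integral,ref_peak optional reference response (e.g. the initial
#'   stimulus); when given, the ratio is normalized by the reference ratio.
#' @return scalar ratio.
#' @export
activity_ratio <- function(sd_integral, peak_dff0,
                           ref_integral = NULL, ref_peak = NULL) {
  if (any(peak_dff0 <= 0)) stop("`peak_dff0` must be > 0")
  r <- sd_integral / peak_dff0
  if (!is.null(ref_integral)) {
    if (is.null(ref_peak) || ref_peak <= 0)
      stop("`ref_peak` must be > 0 when normalizing")
    r <- r / (ref_integral / ref_peak)
  }
  r
}

#' Rise/fall kinetics of a global trace
#'
#' Locates the post-stimulus peak and measures the 20%-to-80% rise time
#' (pre-peak) and the 80%-to-20% fall time (post-peak), with threshold
#' crossings found by linear interpolation.  Levels are fractions of the
#' baseline-to-peak amplitude, where the baseline is the mean of the
#' pre-stimulus samples (zero when there are none — the natural dF/F0
#' baseline).
#'
#' @param trace a [puff_trace] (typically dF/F0).
#' @param t_stimulus stimulus time (s); the peak is searched after it.
#' @return object of class `kinetics_summary` with `peak_dff0`, `t_peak`,
#'   `rise_20_80`, `fall_80_20` (each `NA` where undefined, e.g. a monotone
#'   tail never falling back to 20%).
#' @export
kinetics <- function(trace, t_stimulus = 0) {
  ok <- is.finite(trace$values)
  tt <- trace$times[ok]; vv <- trace$values[ok]
  pre <- tt < t_stimulus
  base <- if (any(pre)) mean(vv[pre]) else 0  # dF/F0 baseline is zero
  post <- which(tt >= t_stimulus)
  if (!length(post)) stop("no samples after t_stimulus")
  ip <- post[which.max(vv[post])]
  peak <- vv[ip]; t_peak <- tt[ip]
  amp <- peak - base
  if (amp <= 0) {
    return(structure(list(peak_dff0 = peak, t_peak = t_peak,
                          rise_20_80 = NA_real_, fall_80_20 = NA_real_,
                          baseline = base),
                     class = "kinetics_summary"))
  }
  lvl <- function(f) base + f * amp
  cross_up <- function(idx, level) {
    # last upward crossing of `level` before the peak
    below <- vv[idx] < level
    ci <- which(below[-length(idx)] & !below[-1])
    if (!length(ci)) return(NA_real_)
    i <- idx[max(ci)]
    tt[i] + (level - vv[i]) / (vv[i + 1] - vv[i]) * (tt[i + 1] - tt[i])
  }
  cross_down <- function(idx, level) {
    # first downward crossing of `level` after the peak
    above <- vv[idx] > level
    ci <- which(above[-length(idx)] & !above[-1])
    if (!length(ci)) return(NA_real_)
    i <- idx[min(ci)]
    tt[i] + (level - vv[i]) / (vv[i + 1] - vv[i]) * (tt[i + 1] - tt[i])
  }
  rise_idx <- seq(min(post), ip)
  t20 <- cross_up(rise_idx, lvl(0.2))
  t80 <- cross_up(rise_idx, lvl(0.8))
  fall_idx <- seq(ip, length(tt))
  f80 <- cross_down(fall_idx, lvl(0.8))
  f20 <- cross_down(fall_idx, lvl(0.2))
  structure(list(peak_dff0 = peak, t_peak = t_peak,
                 rise_20_80 = if (is.na(t20) || is.na(t80)) NA_real_
                              else t80 - t20,
                 fall_80_20 = if (is.na(f80) || is.na(f20)) NA_real_
                              else f20 - f80,
                 baseline = base),
            class = "kinetics_summary")
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat(sprintf("<kinetics> peak %.3g at t = %.3g s; rise(20-80%%) %s s; fall(80-20%%) %s s\n",
              x$peak_dff0, x$t_peak,
              if (is.na(x$rise_20_80)) "undefined" else
                sprintf("%.3g", x$rise_20_80),
              if (is.na(x$fall_80_20)) "undefined" else
                sprintf("%.3g", x$fall_80_20)))
  invisible(x)
}

#' Time at which puff activity has ceased
#'
#' Convention: the first time after the SD flurry peak at which the SD trace
#' falls below `frac` (default 10%) of its peak value and stays there for at
#' least one window.
#'
#' @param sd_trace whole-cell SD [puff_trace].
#' @param frac fraction of the flurry peak defining "ceased".
#' @param t_stimulus stimulus time (s).
#' @return time in seconds (`NA` if the trace never falls below the level).
#' @export
puff_end_time <- function(sd_trace, frac = 0.1, t_stimulus = 0) {
  ok <- is.finite(sd_trace$values)
  tt <- sd_trace$times[ok]; vv <- sd_trace$values[ok]
  post <- which(tt >= t_stimulus)
  ip <- post[which.max(vv[post])]
  level <- frac * vv[ip]
  after <- seq(ip, length(vv))
  below <- which(vv[after] < level)
  if (!length(below)) return(NA_real_)
  tt[after[min(below)]]
}
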