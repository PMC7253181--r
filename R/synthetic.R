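# Ground-truthed synthetic recordings.
#
# The simulator emulates the phenomenology of a dye-loaded cell imaged on an
# EMCCD: a smooth, spatially uniform global dF/F0 rise over seconds;
# stationary puff sites emitting brief (tens to a few hundreds of ms),
# spatially confined (about 1 um) transients; and camera counts formed as
# gain x Poisson photon noise + black offset + Gaussian read noise.  Every
# movie comes with the event table and noiseless traces that generated it,
# so each analysis stage can be checked against known truth.

set_sim_seed <- function(seed) {
  if (is.null(seed) || !is.finite(seed))
    stop("a `seed` is required for reproducible simulation")
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

#' Default puff-site table
#'
#' Sites on a fixed lattice away from the frame borders, all with the default
#' kernel (sigma 1 um, 20 ms rise, 60 ms decay, local peak amplitude 0.5
#' dF/F0) and an event rate that follows an inverted-U in the global dF/F0
#' (maximal around dF/F0 = 2).
#'
#' @param n_sites number of sites (default 24, the typical count of active
#'   hot-spot ROIs monitored per cell).
#' @param shape movie shape `c(T, Y, X)`.
#' @param amplitude local peak amplitude per event (dF/F0).
#' @param rate_max peak event rate per site (Hz).
#' @return data frame of site parameters.
#' @export
default_puff_sites <- function(n_sites = 24, shape = c(1250, 48, 48),
                               amplitude = 0.5, rate_max = 10) {
  Y <- shape[2]; X <- shape[3]
  g <- ceiling(sqrt(n_sites))
  ys <- round(seq(Y * 0.2, Y * 0.8, length.out = g))
  xs <- round(seq(X * 0.2, X * 0.8, length.out = g))
  pos <- expand.grid(y = ys, x = xs)[seq_len(n_sites), ]
  data.frame(site = seq_len(n_sites), y = pos$y, x = pos$x,
             sigma_um = 1, amplitude = amplitude,
             rise_ms = 20, decay_ms = 60,
             rate_max = rate_max, rate_profile = "invU",
             stringsAsFactors = FALSE)
}

#' Synthetic recording configuration
#'
#' Collects the full generative description of a simulated recording.  The
#' defaults emulate a TIRF recording of a dye-loaded cell: 125 frames/s,
#' 0.53 um/pixel, a global rise peaking at 6.9 dF/F0 a few seconds after
#' stimulus onset with first-order removal at 0.22 1/s, and puff sites whose
#' transients last tens to a couple of hundred ms and span about 1 um.
#'
#' @param shape `c(T, Y, X)` movie dimensions.
#' @param frame_interval seconds/frame.
#' @param pixel_size um/pixel.
#' @param baseline baseline fluorescence in mean photons/frame/pixel (scalar
#'   or Y x X map).
#' @param global_rise list: `amplitude` (peak dF/F0; 0 disables), `onset_s`
#'   (stimulus time, s), `rise_tau_s` (sigma of the smooth Gaussian release
#'   pulse driving the rise, s), `removal_k` (1/s).  Defaults give a 20-80%
#'   rise time of about 0.7 s.
#' @param puff_sites data frame as from [default_puff_sites()], or `NULL`
#'   for none.
#' @param camera list: `gain` (counts/photon), `black_level` (counts),
#'   `read_sigma` (counts).
#' @param saturation_dff optional phenomenological dye-saturation ceiling (a
#'   Michaelis term caps the combined dF/F0 at this value); `Inf` disables.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(shape = c(1250, 48, 48),
                             frame_interval = 0.008,
                             pixel_size = 0.53,
                             baseline = 100,
                             global_rise = list(amplitude = 6.9, onset_s = 2,
                                                rise_tau_s = 0.5,
                                                removal_k = 0.22),
                             puff_sites = default_puff_sites(shape = shape),
                             camera = list(gain = 5, black_level = 100,
                                           read_sigma = 0),
                             saturation_dff = Inf) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("`shape` must be c(T, Y, X)")
  if (frame_interval <= 0 || pixel_size <= 0)
    stop("frame_interval and pixel_size must be > 0")
  if (is.matrix(baseline)) {
    if (!identical(dim(baseline), shape[2:3]))
      stop("baseline map shape must match (Y, X)")
  } else if (length(baseline) != 1L || baseline <= 0)
    stop("`baseline` must be a positive scalar or a Y x X map")
  gr <- utils::modifyList(list(amplitude = 0, onset_s = 0, rise_tau_s = 0.5,
                               removal_k = 0.22), global_rise)
  if (gr$amplitude < 0 || gr$rise_tau_s <= 0 || gr$removal_k <= 0)
    stop("invalid global_rise parameters")
  cam <- utils::modifyList(list(gain = 5, black_level = 100, read_sigma = 0),
                           camera)
  if (cam$gain <= 0 || cam$black_level < 0 || cam$read_sigma < 0)
    stop("invalid camera parameters")
  if (!is.null(puff_sites)) {
    puff_sites <- as.data.frame(puff_sites)
    need <- c("y", "x", "sigma_um", "amplitude", "rise_ms", "decay_ms")
    if (!all(need %in% names(puff_sites)))
      stop("puff_sites must have columns ", paste(need, collapse = ", "))
    if (any(puff_sites$y < 1 | puff_sites$y > shape[2] |
            puff_sites$x < 1 | puff_sites$x > shape[3]))
      stop("puff site positions out of bounds")
    if (any(puff_sites$amplitude < 0) || any(puff_sites$sigma_um <= 0) ||
        any(puff_sites$rise_ms <= 0) || any(puff_sites$decay_ms <= 0))
      stop("invalid puff site parameters")
    if (is.null(puff_sites$site)) puff_sites$site <- seq_len(nrow(puff_sites))
    if (is.null(puff_sites$rate_max)) puff_sites$rate_max <- 10
    if (is.null(puff_sites$rate_profile)) puff_sites$rate_profile <- "invU"
  }
  structure(list(shape = shape, frame_interval = frame_interval,
                 pixel_size = pixel_size, baseline = baseline,
                 global_rise = gr, puff_sites = puff_sites, camera = cam,
                 saturation_dff = saturation_dff),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> %d frames of %d x %d px at %.4g s/frame\n",
              x$shape[1], x$shape[2], x$shape[3], x$frame_interval))
  cat(sprintf("  global rise: %.3g dF/F0 (onset %.3g s, tau %.3g s, k %.3g 1/s)\n",
              x$global_rise$amplitude, x$global_rise$onset_s,
              x$global_rise$rise_tau_s, x$global_rise$removal_k))
  cat(sprintf("  puff sites: %d; camera gain %.3g, black %.4g, read sigma %.3g\n",
              if (is.null(x$puff_sites)) 0L else nrow(x$puff_sites),
              x$camera$gain, x$camera$black_level, x$camera$read_sigma))
  invisible(x)
}

# Global dF/F0 time course: the smooth solution of the removal model
# dG/dt = r(t) - k G driven by a Gaussian release pulse (sigma = rise_tau_s,
# centred 3 sigma after onset so it switches on smoothly), normalized so the
# peak equals `amplitude`.  Being infinitely differentiable, a puff-free
# global rise carries no energy into the 3-20 Hz analysis band, matching the
# behaviour of a smoothly graded Ca2+ elevation.
global_dff <- function(times, gr) {
  if (gr$amplitude <= 0) return(numeric(length(times)))
  dt <- if (length(times) > 1) times[2] - times[1] else 1
  tc <- gr$onset_s + 3 * gr$rise_tau_s
  r <- exp(-(times - tc)^2 / (2 * gr$rise_tau_s^2))
  G <- integrate_removal_ode(r, gr$removal_k, dt)
  gr$amplitude * G / max(G)
}

# event temporal kernel, peak-normalized; support to 1e-3 of peak
event_kernel <- function(rise_s, decay_s, dt) {
  tmax <- rise_s * log1p(decay_s / rise_s)  # argmax of (1-e^-u/r) e^-u/d
  kmax <- (1 - exp(-tmax / rise_s)) * exp(-tmax / decay_s)
  u <- seq(0, tmax + decay_s * 8, by = dt)
  k <- (1 - exp(-u / rise_s)) * exp(-u / decay_s) / kmax
  last <- max(which(k > 1e-3))
  list(kernel = k[seq_len(last)], t_peak = tmax,
       duration = dt * sum(k >= 0.1 * max(k)))  # time above 10% of peak
}

# inverted-U event-rate modulation in the global dF/F0 (maximal at dF/F0 = 2)
rate_invU <- function(g) {
  r <- (g / 2) * exp(1 - g / 2)
  r[g <= 0] <- 0
  r
}

#' Simulate a ground-truthed recording
#'
#' Generates the photon-rate movie
#' `baseline * (1 + global(t) + sum of puff transients)`, then camera counts
#' `gain * Poisson(rate) + black + Gaussian read noise`.  The same seed
#' always yields the identical movie.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed (required).
#' @return list with elements
#'   * `movie`: the [movie_stack] (counts, with camera metadata and
#'     `t0_stimulus` at the global onset frame);
#'   * `truth`: ground truth — `events` (site, y, x, onset_s, duration_s,
#'     amplitude), `dff_global` and `dff_true` (noiseless whole-frame mean
#'     dF/F0) traces, `release_rate` trace (from the removal model), `k`,
#'     `gain`.
#' @export
simulate_movie <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set_sim_seed(seed)
  T_ <- config$shape[1]; Y <- config$shape[2]; X <- config$shape[3]
  dt <- config$frame_interval
  times <- (seq_len(T_) - 1) * dt
  g <- global_dff(times, config$global_rise)
  dff <- matrix(g, T_, Y * X)  # T x (Y*X), spatially uniform global part
  events <- list()
  sites <- config$puff_sites
  if (!is.null(sites) && nrow(sites)) {
    yy <- matrix(seq_len(Y), Y, X)
    xx <- matrix(seq_len(X), Y, X, byrow = TRUE)
    for (s in seq_len(nrow(sites))) {
      st <- sites[s, ]
      sig_px <- st$sigma_um / config$pixel_size
      spat <- exp(-((yy - st$y)^2 + (xx - st$x)^2) / (2 * sig_px^2))
      kern <- event_kernel(st$rise_ms / 1000, st$decay_ms / 1000, dt)
      rate <- if (identical(st$rate_profile, "invU")) st$rate_max * rate_invU(g)
              else rep(st$rate_max, T_)
      n_ev <- stats::rpois(T_, rate * dt)
      ev_frames <- rep(which(n_ev > 0), n_ev[n_ev > 0])
      for (fr in ev_frames) {
        idx <- fr + seq_along(kern$kernel) - 1L
        keep <- idx <= T_
        dff[idx[keep], ] <- dff[idx[keep], ] +
          st$amplitude * (kern$kernel[keep] %o% as.vector(spat))
        events[[length(events) + 1L]] <-
          data.frame(site = st$site, y = st$y, x = st$x,
                     onset_s = times[fr], t_peak_s = times[fr] + kern$t_peak,
                     duration_s = kern$duration, amplitude = st$amplitude)
      }
    }
  }
  if (is.finite(config$saturation_dff)) {
    sat <- config$saturation_dff
    dff <- sat * dff / (sat + pmax(dff, 0))
  }
  base <- if (is.matrix(config$baseline)) as.vector(config$baseline)
          else rep(config$baseline, Y * X)
  lambda <- sweep(1 + dff, 2, base, "*")
  lambda[lambda < 0] <- 0
  cam <- config$camera
  counts <- cam$gain * stats::rpois(length(lambda), lambda) + cam$black_level
  if (cam$read_sigma > 0)
    counts <- counts + stats::rnorm(length(counts), 0, cam$read_sigma)
  counts <- array(counts, dim = c(T_, Y, X))
  onset_frame <- if (config$global_rise$amplitude > 0)
    max(1L, 1L + floor(config$global_rise$onset_s / dt)) else NULL
  movie <- movie_stack(counts, dt, config$pixel_size, cam$black_level,
                       t0_stimulus = onset_frame)
  # noiseless whole-frame mean dF/F0 (photon-weighted, as a camera would see)
  dff_true <- as.numeric((lambda %*% rep(1, Y * X)) / sum(base)) - 1
  tr_true <- puff_trace(times, dff_true, "dF/F0")
  rel <- reconstruct_release_rate(tr_true, config$global_rise$removal_k,
                                  smoothing_window = 1)
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(site = integer(), y = integer(), x = integer(),
               onset_s = numeric(), t_peak_s = numeric(),
               duration_s = numeric(), amplitude = numeric())
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  rownames(ev) <- NULL
  list(movie = movie,
       truth = list(events = ev,
                    dff_global = puff_trace(times, g, "dF/F0"),
                    dff_true = tr_true,
                    release_rate = rel,
                    k = config$global_rise$removal_k,
                    gain = cam$gain))
}

#' Simulate uniform-intensity noise series
#'
#' Stationary stacks at several mean photon levels, the synthetic stand-in
#' for imaging a uniform fluorescein sample when calibrating the shot-noise
#' scale.
#'
#' @param levels mean photons/frame/pixel per stack (>= 3 values).
#' @param shape `c(T, Y, X)` of each stack.
#' @param gain counts/photon.
#' @param offset camera black level (counts).
#' @param read_sigma Gaussian read noise SD (counts).
#' @param frame_interval seconds/frame.
#' @param pixel_size um/pixel.
#' @param seed integer seed (required).
#' @return list of [movie_stack]s, one per level.
#' @export
simulate_noise_series <- function(levels, shape = c(400, 24, 24), gain = 5,
                                  offset = 100, read_sigma = 0,
                                  frame_interval = 0.008, pixel_size = 0.53,
                                  seed) {
  if (length(levels) < 3) stop("need at least 3 intensity levels")
  if (any(levels < 0)) stop("levels must be >= 0")
  set_sim_seed(seed)
  n <- prod(shape)
  lapply(levels, function(lv) {
    counts <- gain * stats::rpois(n, lv) + offset
    if (read_sigma > 0) counts <- counts + stats::rnorm(n, 0, read_sigma)
    movie_stack(array(counts, dim = shape), frame_interval, pixel_size,
                black_level = offset)
  })
}

#' Simulate a noisy exponential-decay trace
#'
#' `A * exp(-k t) + C` plus Gaussian noise; test input for removal-rate fits.
#'
#' @param A,k,C decay amplitude, rate (1/s, > 0) and offset.
#' @param noise_sigma Gaussian noise SD.
#' @param duration record length (s).
#' @param dt sampling interval (s).
#' @param seed integer seed (required when `noise_sigma > 0`).
#' @return a [puff_trace].
#' @export
simulate_decay_trace <- function(A, k, C = 0, noise_sigma = 0, duration = 20,
                                 dt = 0.05, seed = NULL) {
  if (k <= 0) stop("`k` must be > 0")
  tt <- seq(0, duration, by = dt)
  vv <- A * exp(-k * tt) + C
  if (noise_sigma > 0) {
    set_sim_seed(seed)
    vv <- vv + stats::rnorm(length(vv), 0, noise_sigma)
  }
  puff_trace(tt, vv, "dF/F0")
}

# step the removal ODE dF/dt = r - k F with an exponential-trapezoidal rule
integrate_removal_ode <- function(r, k, dt, F0 = 0) {
  n <- length(r)
  F <- numeric(n); F[1] <- F0
  E <- exp(-k * dt)
  for (i in seq_len(n - 1))
    F[i + 1] <- F[i] * E + dt * (r[i] * E + r[i + 1]) / 2
  F
}

#' Simulate a matched control/puff-suppressed trace pair
#'
#' Builds a control release flux as the sum of a sustained diffuse component
#' (alpha-function time course) and an early punctate pulse, and a suppressed
#' flux with the punctate pulse removed, then integrates both through the
#' removal model `dF/dt = r - k F`.  The punctate pulse is scaled so that the
#' missing release over the initial rise (up to the control peak) is exactly
#' `puff_fraction` of the control release over that window.
#'
#' @param puff_fraction target punctate fraction of the initial release
#'   (\[0, 1)).
#' @param k removal rate constant (1/s).
#' @param dt sampling interval (s).
#' @param duration record length (s).
#' @param diffuse_tau alpha-function time constant of the diffuse flux (s).
#' @param pulse_center,pulse_sigma Gaussian punctate-pulse timing (s).
#' @return list with `dff_control`, `dff_suppressed` ([puff_trace]s) and
#'   `truth` (`fraction` achieved, `t_peak_control`, `k`, and the two release
#'   traces).
#' @export
simulate_flux_pair <- function(puff_fraction, k = 0.22, dt = 0.01,
                               duration = 30, diffuse_tau = 3,
                               pulse_center = 1.5, pulse_sigma = 0.5) {
  if (!(puff_fraction >= 0 && puff_fraction < 1))
    stop("`puff_fraction` must be in [0, 1)")
  tt <- seq(0, duration, by = dt)
  r_d <- (tt / diffuse_tau) * exp(1 - tt / diffuse_tau)       # peak 1
  pulse <- exp(-(tt - pulse_center)^2 / (2 * pulse_sigma^2))  # peak 1
  trapz <- function(y, upto) {
    sel <- tt <= upto
    ys <- y[sel]
    sum(diff(tt[sel]) * (ys[-length(ys)] + ys[-1]) / 2)
  }
  amp <- if (puff_fraction > 0) 1 else 0
  t_end <- NA_real_
  if (puff_fraction > 0) {
    for (it in 1:30) {  # fixed point: pulse area vs fraction at control peak
      r_c <- r_d + amp * pulse
      Fc <- integrate_removal_ode(r_c, k, dt)
      t_end <- tt[which.max(Fc)]
      Id <- trapz(r_d, t_end)
      Ip_target <- puff_fraction / (1 - puff_fraction) * Id
      Ip_cur <- trapz(pulse, t_end)
      amp_new <- Ip_target / Ip_cur
      if (abs(amp_new - amp) < 1e-12) { amp <- amp_new; break }
      amp <- amp_new
    }
  }
  r_c <- r_d + amp * pulse
  Fc <- integrate_removal_ode(r_c, k, dt)
  Fs <- integrate_removal_ode(r_d, k, dt)
  t_end <- tt[which.max(Fc)]
  achieved <- if (puff_fraction > 0)
    (trapz(r_c, t_end) - trapz(r_d, t_end)) / trapz(r_c, t_end) else 0
  list(dff_control = puff_trace(tt, Fc, "dF/F0"),
       dff_suppressed = puff_trace(tt, Fs, "dF/F0"),
       truth = list(fraction = achieved, t_peak_control = t_end, k = k,
                    release_control = puff_trace(tt, r_c, "dF/F0 per s"),
                    release_suppressed = puff_trace(tt, r_d, "dF/F0 per s")))
}
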