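# Shared fixtures, built in code.  Expensive objects (noise calibrations and
# synthetic movies reused by several tests) are memoized for the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# temporal or spatial noise calibration matched to a side x side field
fixture_calibration <- function(side, pipeline = "temporal",
                                gain = 5, offset = 100) {
  cached(paste0("cal_", pipeline, "_", side), {
    T_ <- max(400, ceiling(1.1e6 / side^2))  # >= 1e6 voxels per level
    stacks <- simulate_noise_series(c(30, 100, 250, 500, 900),
                                    shape = c(T_, side, side),
                                    gain = gain, offset = offset,
                                    seed = 9000 + side)
    calibrate_noise_scale(stacks, filter_params(), pipeline = pipeline)
  })
}

# default-condition synthetic recording with puffs (48 x 48, 10 s)
fixture_puff_sim <- function() {
  cached("puff_sim", simulate_movie(synthetic_config(), seed = 101))
}

# matched puff-free (ionomycin-like) control: same global rise, no sites
fixture_control_sim <- function() {
  cached("control_sim",
         simulate_movie(synthetic_config(puff_sites = NULL), seed = 102))
}

full_mask <- function(side) roi_mask(matrix(TRUE, side, side))

# analytic white-noise power (variance) fraction passed by the temporal
# blur + band-pass chain, including reflective-boundary effects, from the
# filter frequency response -- independent of the pipeline implementation
analytic_band_fraction <- function(params, fs, side) {
  bf <- signal::butter(params$butter_order,
                       c(params$band_low, params$band_high) / (fs / 2),
                       type = "pass")
  h <- Mod(signal::freqz(bf$b, bf$a, n = 16384, Fs = fs)$h)
  passes <- if (params$zero_phase) 4 else 2
  frac_t <- mean(h^passes)
  k1 <- exp(-(seq(-floor(4 * params$spatial_sigma),
                  floor(4 * params$spatial_sigma)))^2 /
              (2 * params$spatial_sigma^2))
  k1 <- k1 / sum(k1)
  # per-pixel sum of squared blur weights with mirrored borders
  r <- (length(k1) - 1) / 2
  wsq <- vapply(seq_len(side), function(i) {
    src <- i + seq(-r, r)
    src <- ifelse(src < 1, 2 - src, src)
    src <- ifelse(src > side, 2 * side - src, src)
    sum(tapply(k1, src, sum)^2)
  }, numeric(1))
  frac_t * mean(wsq)^2
}

# literal re-implementation of the temporal SD definition with explicit
# per-pixel / per-window loops; independent oracle for temporal_sd_stack
brute_force_sd_stack <- function(movie, params, calibration = NULL) {
  d <- dim(movie$data); T_ <- d[1]; Y <- d[2]; X <- d[3]
  w <- params$window_frames
  fs <- 1 / movie$frame_interval
  bs <- movie$data - movie$black_level
  # truncated-Gaussian blur, frame by frame, pixel by pixel
  r <- floor(4 * params$spatial_sigma)
  k1 <- exp(-(-r:r)^2 / (2 * params$spatial_sigma^2)); k1 <- k1 / sum(k1)
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i <- ifelse(i < 1, 2 - i, i)
      i <- ifelse(i > n, 2 * n - i, i)
    }
    i
  }
  g <- array(0, d)
  for (t in seq_len(T_)) {
    tmp <- matrix(0, Y, X)
    for (y in seq_len(Y)) for (x in seq_len(X))
      tmp[y, x] <- sum(k1 * bs[t, refl(y + (-r:r), Y), x])
    for (y in seq_len(Y)) for (x in seq_len(X))
      g[t, y, x] <- sum(k1 * tmp[y, refl(x + (-r:r), X)])
  }
  # zero-phase Butterworth band-pass, pixel by pixel, with odd reflection
  bf <- signal::butter(params$butter_order,
                       c(params$band_low, params$band_high) / (fs / 2),
                       type = "pass")
  rt <- max(Mod(polyroot(rev(bf$a))))
  p <- min(T_ - 1, max(ceiling(log(1e-6) / log(rt)), 3 * length(bf$b)))
  g0 <- sum(bf$b) / sum(bf$a)
  run <- function(v) as.numeric(
    signal::filter(bf$b, bf$a, v,
                   init.x = rep(v[1], length(bf$b) - 1),
                   init.y = rep(v[1] * g0, length(bf$a) - 1)))
  f <- array(0, d)
  for (y in seq_len(Y)) for (x in seq_len(X)) {
    v <- g[, y, x]
    vp <- c(2 * v[1] - v[(p + 1):2], v, 2 * v[T_] - v[(T_ - 1):(T_ - p)])
    fb <- rev(run(rev(run(vp))))
    f[, y, x] <- fb[p + seq_len(T_)]
  }
  # running moments, explicit windows, centre-aligned
  out <- array(NA_real_, d)
  scale <- if (is.null(calibration)) 0 else calibration$sd_slope
  for (y in seq_len(Y)) for (x in seq_len(X)) {
    for (j in seq_len(T_ - w + 1)) {
      centre <- j + (w - 1) %/% 2
      win <- j:(j + w - 1)
      fv <- f[win, y, x]
      va <- mean(fv^2) - mean(fv)^2
      mu <- mean(g[win, y, x])
      out[centre, y, x] <- sqrt(max(va, 0)) - scale * sqrt(max(mu, 0))
    }
  }
  guard <- ceiling(fs / params$band_low)
  out[c(seq_len(guard), (T_ - guard + 1):T_), , ] <- NA_real_
  out
}
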