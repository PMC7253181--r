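test_that("calibration validates its inputs", {
  p <- filter_params()
  two <- simulate_noise_series(c(50, 100, 200), shape = c(200, 8, 8),
                               seed = 1)[1:2]
  expect_error(calibrate_noise_scale(two, p), "at least 3")
  # noise-free constant stacks at distinct levels -> slope and scale 0
  const <- lapply(c(100, 200, 400), function(v)
    movie_stack(array(v, dim = c(200, 8, 8)), 0.008))
  cal0 <- calibrate_noise_scale(const, p)
  expect_equal(cal0$slope, 0, tolerance = 1e-12)
  expect_equal(cal0$scale_c, 0, tolerance = 1e-8)
  expect_equal(cal0$sd_slope, 0, tolerance = 1e-12)
  # degenerate: all levels identical
  same <- lapply(1:3, function(i)
    movie_stack(array(100, dim = c(200, 8, 8)), 0.008))
  expect_error(calibrate_noise_scale(same, p), "degenerate")
})

test_that("calibration is linear in intensity with scale_c = sqrt(slope)", {
  cal <- fixture_calibration(24)
  expect_gt(cal$slope, 0)
  expect_equal(cal$scale_c, sqrt(cal$slope))
  expect_gt(cal$r_squared, 0.99)
  expect_equal(cal$n_levels, 5)
  # JSON round trip
  f <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, f)
  back <- read_calibration(f)
  expect_equal(back$slope, cal$slope)
  expect_equal(back$sd_slope, cal$sd_slope)
})

test_that("temporal SD stack equals the explicit-loop oracle", {
  p <- filter_params()
  set.seed(6)
  movie <- movie_stack(array(rpois(120 * 8 * 8, 200) + rnorm(120 * 64, 0, 2),
                             dim = c(120, 8, 8)),
                       frame_interval = 0.008, black_level = 50)
  cal <- fixture_calibration(24)  # any scale exercises the correction term
  got <- temporal_sd_stack(movie, p, cal)
  want <- brute_force_sd_stack(movie, p, cal)
  ok <- !is.na(want)
  expect_equal(which(is.na(got$data)), which(is.na(want)))
  expect_lt(max(abs(got$data[ok] - want[ok]) / (abs(want[ok]) + 1e-8)), 1e-6)
})

test_that("corrected SD of pure shot noise is centred on zero", {
  p <- filter_params()
  cal <- fixture_calibration(24)
  means <- sapply(1:5, function(r) {
    mv <- simulate_noise_series(rep(200, 3), shape = c(300, 24, 24),
                                seed = 300 + r)[[1]]
    mean(temporal_sd_stack(mv, p, cal)$data, na.rm = TRUE)
  })
  sem <- sqrt(var(means) / length(means) +
                (cal$sd_slope_se * sqrt(5 * 200))^2)
  expect_lt(abs(mean(means)), 3 * sem)
})

test_that("SD hotspot localizes an injected puff to the pixel", {
  # single site, clean conditions: blob sigma ~1.5 px, 20% dF/F0, ~100 ms
  sites <- data.frame(site = 1, y = 16, x = 16, sigma_um = 0.8,
                      amplitude = 0.2, rise_ms = 20, decay_ms = 40,
                      rate_max = 0.8, rate_profile = "const")
  cfg <- synthetic_config(shape = c(800, 32, 32),
                          global_rise = list(amplitude = 0),
                          puff_sites = sites, baseline = 300)
  sim <- simulate_movie(cfg, seed = 31)
  cal <- fixture_calibration(32)
  sds <- temporal_sd_stack(sim$movie, filter_params(), cal)
  m <- match_events_to_sd(sds, sim$truth$events)
  expect_gt(m$n_scored, 2)
  expect_true(all(abs(m$dy) <= 1 & abs(m$dx) <= 1))
  expect_true(all(abs(m$dframe) <= filter_params()$window_frames / 2))
})

test_that("doubling puff amplitude never decreases the peak whole-cell SD", {
  cal <- fixture_calibration(32)
  amps <- c(0.1, 0.2, 0.4, 0.8, 1.6)
  peaks <- sapply(amps, function(a) {
    sites <- default_puff_sites(6, shape = c(700, 32, 32), amplitude = a)
    cfg <- synthetic_config(shape = c(700, 32, 32), puff_sites = sites,
                            global_rise = list(amplitude = 3, onset_s = 1.5,
                                               rise_tau_s = 0.5,
                                               removal_k = 0.22))
    sim <- simulate_movie(cfg, seed = 77)  # same seed: paired comparison
    sds <- temporal_sd_stack(sim$movie, filter_params(), cal)
    max(roi_trace(sds, full_mask(32))$values, na.rm = TRUE)
  })
  expect_true(all(diff(peaks) > 0))
})

test_that("spatially uniform flicker produces no spatial SD", {
  # every pixel follows the identical time course -> zero spatial variance
  T_ <- 300
  tc <- 200 + 50 * sin(2 * pi * 6 * (0:(T_ - 1)) * 0.008)
  mv <- movie_stack(array(rep(tc, 16 * 16), dim = c(T_, 16, 16)), 0.008)
  tr <- spatial_sd_trace(mv, full_mask(16), filter_params())
  expect_lt(max(abs(tr$values), na.rm = TRUE), 1e-8)
})

test_that("spatial SD of calibrated shot noise is centred on zero", {
  p <- filter_params()
  calS <- fixture_calibration(24, pipeline = "spatial")
  means <- sapply(1:5, function(r) {
    mv <- simulate_noise_series(rep(250, 3), shape = c(300, 24, 24),
                                seed = 500 + r)[[1]]
    mean(spatial_sd_trace(mv, full_mask(24), p, calS)$values, na.rm = TRUE)
  })
  sem <- sqrt(var(means) / length(means) +
                (calS$sd_slope_se * sqrt(5 * 250))^2)
  expect_lt(abs(mean(means)), 3 * sem)
})

test_that("spatial and temporal SD traces agree on a puff recording", {
  sim <- fixture_puff_sim()
  p <- filter_params()
  tr_t <- roi_trace(temporal_sd_stack(sim$movie, p,
                                      fixture_calibration(48)),
                    full_mask(48))
  tr_s <- spatial_sd_trace(sim$movie, full_mask(48), p,
                           fixture_calibration(48, pipeline = "spatial"))
  ok <- is.finite(tr_t$values) & is.finite(tr_s$values)
  expect_gt(cor(tr_t$values[ok], tr_s$values[ok]), 0.8)
})

test_that("temporal SD stack and calibration reject mismatched pipelines", {
  calS <- fixture_calibration(24, pipeline = "spatial")
  mv <- simulate_noise_series(rep(100, 3), shape = c(200, 24, 24),
                              seed = 1)[[1]]
  expect_error(temporal_sd_stack(mv, filter_params(), calS), "pipeline")
  expect_error(spatial_sd_trace(mv, full_mask(24), filter_params(),
                                fixture_calibration(24)), "pipeline")
})

test_that("power spectrum satisfies Parseval and finds a pure tone", {
  fs <- 125
  tt <- seq(0, 8 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * tt)
  ps <- power_spectrum(list(puff_trace(tt, x)), highpass_cutoff = 0)
  expect_equal(ps$frequencies[which.max(ps$power)], 10, tolerance = ps$df)
  xd <- x - mean(x)
  expect_equal(sum(ps$power) * ps$df, mean(xd^2), tolerance = 0.01)
  expect_error(power_spectrum(list(puff_trace(tt[1:32], x[1:32]))), "64")
})

test_that("white-noise spectrum is flat above the high-pass corner", {
  set.seed(8)
  traces <- lapply(1:150, function(i) rnorm(512))
  ps <- power_spectrum(traces, fs = 125, highpass_cutoff = 1)
  sel <- ps$frequencies > 3 & ps$frequencies < 55
  fit <- lm(log(ps$power[sel]) ~ log(ps$frequencies[sel]))
  expect_lt(abs(coef(fit)[2]), 0.1)
})
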