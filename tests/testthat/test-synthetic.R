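test_that("camera model: count mean and variance match the analytic values", {
  g <- 5; lam <- 120; rs <- 3; off <- 100
  st <- simulate_noise_series(c(lam, lam, lam), shape = c(500, 24, 24),
                              gain = g, offset = off, read_sigma = rs,
                              seed = 40)[[1]]
  n <- length(st$data)
  mu_th <- g * lam + off
  var_th <- g^2 * lam + rs^2
  expect_lt(abs(mean(st$data) - mu_th), 3 * sqrt(var_th / n))
  # variance of the sample variance ~ 2 var^2 / n for near-Gaussian counts
  expect_lt(abs(var(as.vector(st$data)) - var_th),
            3 * sqrt(2 * var_th^2 / n))
})

test_that("same seed reproduces the movie bit-for-bit, different seeds differ", {
  cfg <- synthetic_config(shape = c(150, 16, 16))
  a <- simulate_movie(cfg, seed = 7)
  b <- simulate_movie(cfg, seed = 7)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$truth$events, b$truth$events)
  c_ <- simulate_movie(cfg, seed = 8)
  expect_false(identical(a$movie$data, c_$movie$data))
  # and the float32 TIFF bytes are identical across runs
  f1 <- withr::local_tempfile(fileext = ".tif")
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_stack(a$movie, f1); write_stack(b$movie, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("simulation without sources is stationary noise with null SD", {
  cfg <- synthetic_config(shape = c(300, 24, 24),
                          global_rise = list(amplitude = 0),
                          puff_sites = NULL)
  sim <- simulate_movie(cfg, seed = 9)
  expect_equal(nrow(sim$truth$events), 0)
  sds <- temporal_sd_stack(sim$movie, filter_params(),
                           fixture_calibration(24))
  m <- mean(sds$data, na.rm = TRUE)
  raw <- mean(temporal_sd_stack(sim$movie, filter_params())$data,
              na.rm = TRUE)
  expect_lt(abs(m), 0.05 * raw)  # corrected to a few % of the raw SD
})

test_that("ground-truth event table matches the emitted transients", {
  sites <- data.frame(site = 1, y = 16, x = 16, sigma_um = 1,
                      amplitude = 0.5, rise_ms = 20, decay_ms = 60,
                      rate_max = 1, rate_profile = "const")
  cfg <- synthetic_config(shape = c(1200, 32, 32),
                          global_rise = list(amplitude = 0),
                          puff_sites = sites)
  sim <- simulate_movie(cfg, seed = 13)
  ev <- sim$truth$events
  expect_gt(nrow(ev), 3)
  expect_true(all(ev$y == 16 & ev$x == 16))
  expect_true(all(ev$duration_s > 0.02 & ev$duration_s < 0.5))
  expect_true(all(ev$t_peak_s > ev$onset_s))
  # events leave a real fluorescence footprint at the site
  bs <- subtract_black(sim$movie)
  base <- median(bs$data[, 16, 16])
  fr <- 1 + round(ev$t_peak_s / 0.008)
  expect_true(all(bs$data[fr, 16, 16] > base))
})

test_that("config validation rejects inconsistent parameters", {
  expect_error(synthetic_config(shape = c(0, 8, 8)), "shape")
  expect_error(synthetic_config(frame_interval = 0), "frame_interval")
  expect_error(synthetic_config(baseline = -5), "baseline")
  bad <- default_puff_sites(2, shape = c(100, 16, 16))
  bad$y[1] <- 99
  expect_error(synthetic_config(shape = c(100, 16, 16), puff_sites = bad),
               "bounds")
  expect_error(simulate_movie(synthetic_config(shape = c(100, 16, 16)),
                              seed = NULL), "seed")
})

test_that("dye saturation caps the emitted dF/F0", {
  sites <- NULL
  cfg_lin <- synthetic_config(shape = c(400, 16, 16), puff_sites = NULL)
  cfg_sat <- synthetic_config(shape = c(400, 16, 16), puff_sites = NULL,
                              saturation_dff = 4)
  lin <- simulate_movie(cfg_lin, seed = 3)
  sat <- simulate_movie(cfg_sat, seed = 3)
  expect_equal(max(lin$truth$dff_true$values), 6.9, tolerance = 1e-6)
  expect_lt(max(sat$truth$dff_true$values), 4)
})

test_that("flux pair: requested punctate fraction is realized exactly", {
  p0 <- simulate_flux_pair(0)
  expect_equal(p0$dff_control$values, p0$dff_suppressed$values)
  expect_equal(p0$truth$fraction, 0)
  p41 <- simulate_flux_pair(0.41)
  expect_equal(p41$truth$fraction, 0.41, tolerance = 0.01)
  got <- punctate_fraction_initial(p41$truth$release_control,
                                   p41$truth$release_suppressed,
                                   p41$truth$t_peak_control)
  expect_equal(got, p41$truth$fraction, tolerance = 1e-9)
  # heavy suppression: most early release is punctate
  p9 <- simulate_flux_pair(0.9)
  expect_equal(p9$truth$fraction, 0.9, tolerance = 0.02)
  expect_error(simulate_flux_pair(1), "puff_fraction")
})

test_that("simulator-analyzer round trip: movie truth supports flux recovery", {
  sim <- fixture_control_sim()
  dff <- sim$truth$dff_true
  rec <- reconstruct_release_rate(dff, sim$truth$k, smoothing_window = 1)
  # the reconstruction of the true trace matches the stored truth exactly
  expect_equal(rec$values, sim$truth$release_rate$values)
  # and the decay tail yields the programmed k
  pk <- which.max(dff$values)
  fit <- fit_exponential_decay(dff, c(dff$times[pk] + 2,
                                      max(dff$times)))
  expect_equal(fit$k, sim$truth$k, tolerance = 0.05 * sim$truth$k)
})
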