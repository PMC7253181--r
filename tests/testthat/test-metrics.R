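test_that("dF/F0 basics: zero at baseline, one at doubled F, gain-invariant", {
  tt <- seq(0, 9.9, by = 0.1)
  f0 <- rep(200, 50)
  tr <- puff_trace(tt, c(f0, rep(400, 50)), "F")
  dff <- compute_dff0(tr, baseline_frames = 50)
  expect_equal(dff$values[1:50], rep(0, 50))
  expect_equal(dff$values[51:100], rep(1, 50))
  # scaling F by any camera gain leaves dF/F0 unchanged, exactly
  tr_g <- puff_trace(tt, tr$values * 7.3)
  expect_equal(compute_dff0(tr_g, baseline_frames = 50)$values, dff$values)
  expect_error(compute_dff0(puff_trace(tt, rep(0, 100)), 50), "eps")
})

test_that("movie dF/F0 recovers the programmed global peak", {
  sim <- fixture_control_sim()  # smooth rise to 6.9 dF/F0, no puffs
  tr <- roi_trace(subtract_black(sim$movie), full_mask(48))
  dff <- compute_dff0(tr, baseline_frames = 100)
  expect_equal(max(dff$values), 6.9, tolerance = 0.05 * 6.9)
  # pixel-wise movie normalization agrees with the trace route
  dff_mov <- compute_dff0(sim$movie, baseline_frames = 100)
  tr2 <- roi_trace(dff_mov, full_mask(48), units = "dF/F0")
  expect_equal(max(tr2$values), max(dff$values), tolerance = 0.02)
})

test_that("roi_trace averages masked pixels", {
  a <- array(0, dim = c(3, 4, 4))
  a[, , 1:2] <- 2; a[, , 3:4] <- 6
  st <- movie_stack(a, 0.1)
  expect_equal(roi_trace(st, full_mask(4))$values, rep(4, 3))
  m1 <- matrix(FALSE, 4, 4); m1[2, 2] <- TRUE
  a[2, 2, 2] <- 99
  expect_equal(roi_trace(movie_stack(a, 0.1), roi_mask(m1))$values,
               c(2, 99, 2))
  expect_equal(roi_trace(st, roi_mask(m1))$times, c(0, 0.1, 0.2))
})

test_that("binned scatter: constant SD over a monotone rise gives flat bins", {
  tt <- seq(0, 3, by = 0.01)
  dff <- puff_trace(tt, tt)           # rises 0 -> 3
  sdv <- puff_trace(tt, rep(1, length(tt)))
  sc <- sd_vs_dff_scatter(sdv, dff, t_start = 0, t_peak = 3)
  occ <- !is.na(sc$mean_sd)
  expect_true(any(occ))
  expect_true(all(abs(sc$mean_sd[occ] - 1) < 1e-12))
  expect_equal(diff(sc$bin_edges)[1], 0.1)
  expect_error(sd_vs_dff_scatter(sdv, dff, t_start = 5, t_peak = 6),
               "window|samples")
})

test_that("binned scatter reproduces an inverted-U peaking near dF/F0 = 2", {
  # built so the SD is maximal when the concurrent dF/F0 passes 2
  tt <- seq(0, 5, by = 0.008)
  dff <- puff_trace(tt, 6.9 * (tt / 5)^1.5)
  sdv <- puff_trace(tt, (dff$values / 2) * exp(1 - dff$values / 2) +
                      rnorm(length(tt), 0, 0.02))
  set.seed(9)
  sc <- sd_vs_dff_scatter(sdv, dff, t_start = 0, normalize = TRUE)
  occ <- which(!is.na(sc$mean_sd))
  argmax <- sc$bin_mid[occ[which.max(sc$mean_sd[occ])]]
  expect_lt(abs(argmax - 2), 0.15)
  expect_equal(max(sc$mean_sd, na.rm = TRUE), 1)
  # inverted-U: rises before the argmax bin, falls after
  expect_gt(sc$mean_sd[occ][which.max(sc$mean_sd[occ])],
            sc$mean_sd[occ][1])
  expect_gt(max(sc$mean_sd[occ]), sc$mean_sd[occ][length(occ)])
})

test_that("binned scatter is stable under resampling", {
  tt <- seq(0, 5, by = 0.02)
  dff_v <- 4 * (tt / 5)
  sd_v <- sin(pi * tt / 5)
  sc1 <- sd_vs_dff_scatter(puff_trace(tt, sd_v), puff_trace(tt, dff_v), 0)
  t2 <- seq(0, 5, by = 0.01)
  sc2 <- sd_vs_dff_scatter(puff_trace(t2, sin(pi * t2 / 5)),
                           puff_trace(t2, 4 * t2 / 5), 0)
  occ <- !is.na(sc1$mean_sd) & !is.na(sc2$mean_sd)
  # per-bin means shift by <2% of the trace maximum under 2x oversampling
  expect_lt(max(abs(sc1$mean_sd[occ] - sc2$mean_sd[occ])),
            0.02 * max(abs(sc1$mean_sd), na.rm = TRUE))
})

test_that("activity integral matches a fine rectangle-sum oracle", {
  tt <- seq(0, 3, by = 0.05)
  expect_equal(puff_activity_integral(puff_trace(tt, rep(0, length(tt))),
                                      0, 3), 0)
  expect_equal(puff_activity_integral(puff_trace(tt, rep(2, length(tt))),
                                      0, 3), 6)
  set.seed(11)
  v <- as.numeric(stats::filter(rnorm(61), rep(1 / 5, 5), circular = TRUE))
  tr <- puff_trace(tt, v)
  fine <- seq(0.25, 2.75, by = 0.0005)   # 10x-oversampled rectangle sum
  oracle <- sum(approx(tt, v, fine)$y) * 0.0005
  expect_equal(puff_activity_integral(tr, 0.25, 2.75), oracle,
               tolerance = 1e-3)
  expect_error(puff_activity_integral(tr, 2, 5), "outside")
})

test_that("activity ratio divides and normalizes", {
  expect_equal(activity_ratio(6, 3), 2)
  expect_equal(activity_ratio(6, 3, ref_integral = 6, ref_peak = 3), 1)
  expect_error(activity_ratio(6, 0), "peak")
  # proportional decline across repeat stimuli keeps the ratio constant
  ints <- c(10, 8, 6, 4, 2); peaks <- c(5, 4, 3, 2, 1)
  r <- activity_ratio(ints, peaks, ref_integral = 10, ref_peak = 5)
  expect_true(all(abs(r - 1) < 0.1))
})

test_that("kinetics: analytic ramp, exponential fall, degenerate traces", {
  tt <- seq(0, 1, by = 0.01)
  k1 <- kinetics(puff_trace(tt, tt))
  expect_equal(k1$rise_20_80, 0.6, tolerance = 1e-9)
  dec <- simulate_decay_trace(1, 0.32, 0, 0, duration = 20, dt = 0.01)
  k2 <- kinetics(dec)
  expect_equal(k2$fall_80_20, log(4) / 0.32, tolerance = 1e-3)
  flat <- kinetics(puff_trace(tt, rep(0, length(tt))))
  expect_true(is.na(flat$rise_20_80) && is.na(flat$fall_80_20))
  # monotone rise: fall undefined but not an error
  expect_true(is.na(kinetics(puff_trace(tt, tt))$fall_80_20))
})

test_that("time reversal swaps rise and fall", {
  tt <- seq(0, 2, by = 0.01)
  v <- exp(-((tt - 1) / 0.3)^2)  # symmetric-capable but use asymmetric:
  v <- ifelse(tt <= 1, tt, exp(-(tt - 1) * 2))
  k_fwd <- kinetics(puff_trace(tt, v))
  k_rev <- kinetics(puff_trace(tt, rev(v)))
  expect_equal(k_fwd$rise_20_80, k_rev$fall_80_20, tolerance = 1e-9)
  expect_equal(k_fwd$fall_80_20, k_rev$rise_20_80, tolerance = 1e-9)
})

test_that("synthetic recording: rise kinetics near the CCH/i-IP3 regime", {
  sim <- fixture_control_sim()
  tr <- compute_dff0(roi_trace(subtract_black(sim$movie), full_mask(48)),
                     baseline_frames = 100)
  k <- kinetics(tr, t_stimulus = 2)
  expect_equal(k$rise_20_80, 0.75, tolerance = 0.3)  # ~0.7-0.8 s regime
  expect_gt(k$t_peak, 2)
})
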