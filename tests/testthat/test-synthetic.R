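test_that("laser waveforms honor the stated envelope", {
  lw <- make_laser_waveform(80, 0.25, 25)
  # crest need not coincide with a sample; it may undershoot by the grid
  expect_equal(max(lw$samples), 25, tolerance = 1e-4)
  expect_lte(max(lw$samples), 25)
  expect_equal(min(lw$samples), 0)
  expect_identical(lw$samples[1], 0)
  expect_identical(lw$samples[length(lw$samples)], 0)
  expect_true(all(lw$samples >= 0))

  sq <- make_laser_waveform(0, 0.25, 25)
  mid <- sq$samples[round(length(sq$samples) * 0.5)]
  expect_equal(mid, 25)
  t <- seq(0, 0.25, length.out = length(sq$samples))
  plateau <- sq$samples[t > 0.006 & t < 0.244]
  expect_true(all(abs(plateau - 25) < 1e-9))
  expect_lt(sq$samples[round(0.0025 * 25000)], 25)   # inside the taper

  # numerical max |derivative| bounded by the analytic slopes
  for (lw_i in list(lw, sq, make_laser_waveform(40, 0.3, 10,
                                                phase = 1.1))) {
    d <- diff(lw_i$samples) * lw_i$rate
    bound <- pi / (2 * lw_i$taper) * lw_i$peak +
      pi * lw_i$freq * lw_i$peak
    expect_lte(max(abs(d)), bound * 1.01)
  }

  expect_error(make_laser_waveform(80, 0.008, 25), "taper")
  # reproducible (deterministic): identical calls identical samples
  expect_identical(make_laser_waveform(80, 0.25, 25)$samples, lw$samples)
})

test_that("recording simulator places spikes at ground-truth times", {
  # zero units, zero noise: all-zero trace
  z <- simulate_recording(default_sim_config(duration = 0.2,
                                             sites_per_shank = 4L,
                                             noise_sd = 0, pink_sd = 0),
                          seed = 1)
  expect_true(all(z$block$samples == 0))
  expect_equal(nrow(z$block$samples), 4)
  expect_equal(z$block$rate, 25000)

  # one unit, noiseless: trough crossings at exactly the truth times
  units <- data.frame(shank = 1, depth_um = 50, kind = "none",
                      baseline_rate = 20, peak_rate = 0,
                      amplitude_uV = 100)
  sim <- simulate_recording(default_sim_config(duration = 2,
                                               sites_per_shank = 4L,
                                               units = units, noise_sd = 0,
                                               pink_sd = 0), seed = 2)
  truth <- sim$truth$units[[1]]$spike_times
  expect_gt(length(truth), 10)
  ch <- which.max(sim$truth$units[[1]]$channel_weights)
  v <- sim$block$samples[ch, ]
  crossings <- which(v < -50 & c(v[-1], 0) >= -50) / 25000
  expect_equal(length(crossings), length(truth))
  expect_lt(max(abs(crossings - truth)), 0.001)

  expect_error(simulate_recording(
    default_sim_config(sites_per_shank = 4L,
                       units = data.frame(shank = 1, depth_um = 900,
                                          kind = "none", baseline_rate = 5,
                                          peak_rate = 0,
                                          amplitude_uV = 100))),
    "outside probe span")

  # reproducibility
  a <- simulate_recording(default_sim_config(duration = 0.1,
                                             sites_per_shank = 2L), seed = 5)
  b <- simulate_recording(default_sim_config(duration = 0.1,
                                             sites_per_shank = 2L), seed = 5)
  expect_identical(a$block$samples, b$block$samples)
})

test_that("opto-entrained unit concentrates spectral power at 80 Hz", {
  units <- data.frame(shank = 1, depth_um = 25, kind = "opto",
                      baseline_rate = 1, peak_rate = 300,
                      amplitude_uV = 150)
  sim <- simulate_recording(
    default_sim_config(duration = 10, sites_per_shank = 2L, units = units,
                       laser_onsets = seq(0.2, 9.4, by = 0.4),
                       laser = make_laser_waveform(80, 0.25, 25),
                       noise_sd = 0, pink_sd = 0), seed = 7)
  st <- sim$truth$units[[1]]$spike_times
  counts <- tabulate(floor(st * 1000) + 1, nbins = 10000)
  sp <- abs(fft(counts - mean(counts)))^2
  fr <- (seq_along(counts) - 1) / 10
  band <- fr > 5 & fr < 480
  expect_equal(fr[band][which.max(sp[band])], 80, tolerance = 0.02)
})

test_that("eye-trace generator matches its stated kinematics", {
  still <- simulate_eye_trace(NULL, duration = 0.5, jitter_sd = 0, seed = 1)
  expect_true(all(still$eye$x == 0) && all(still$eye$y == 0))

  one <- simulate_eye_trace(data.frame(t = 0.5, amplitude = 8,
                                       direction = 0),
                            duration = 1.5, seed = 2)
  pre <- median(one$eye$x[one$eye$t < 0.45])
  post <- median(one$eye$x[one$eye$t > 0.7])
  expect_equal(post - pre, 8, tolerance = 0.1)
  expect_gt(one$truth$peak_speed, 50)
  # amplitudes >= 0.5 deg clear the velocity threshold
  tiny <- simulate_eye_trace(data.frame(t = 0.3, amplitude = 0.5,
                                        direction = 45),
                             duration = 0.8, jitter_sd = 0, seed = 3)
  expect_gt(tiny$truth$peak_speed, 50)

  blinky <- simulate_eye_trace(NULL, duration = 1,
                               blinks = data.frame(t = 0.4,
                                                   duration = 0.08),
                               seed = 4)
  excurs <- abs(blinky$eye$y) > 10
  expect_true(all(blinky$eye$blink[excurs]))

  expect_error(simulate_eye_trace(data.frame(t = c(0.5, 0.505),
                                             amplitude = c(8, 8),
                                             direction = c(0, 0)),
                                  duration = 1), "overlap")
})

test_that("session generator honors hit probabilities and hazard", {
  # lambda = 0, p = 1: every go trial responds inside the hit window
  s1 <- simulate_detection_session(c(high = 1, low = 1), lambda = 0,
                                   n_trials = 120, seed = 1)
  go <- s1$trials$condition != "catch"
  lat <- s1$trials$response_time[go] - s1$trials$target_on[go]
  expect_false(any(is.na(lat)))
  expect_true(all(lat >= 0.05 & lat < 0.5))
  expect_true(all(is.na(s1$trials$response_time[!go])))

  # lambda = 0, p = 0: silence
  s0 <- simulate_detection_session(c(high = 0, low = 0), lambda = 0,
                                   n_trials = 100, seed = 2)
  expect_true(all(is.na(s0$trials$response_time)))

  # hazard-only: catch response fraction ~ 1 - exp(-0.8 lambda)
  lam <- 0.6
  frac <- vapply(1:4, function(sd) {
    s <- simulate_detection_session(c(high = 0), lambda = lam,
                                    n_trials = 1000, seed = sd)
    ic <- s$trials$condition == "catch"
    mean(!is.na(s$trials$response_time[ic]))
  }, numeric(1))
  p_true <- 1 - exp(-0.8 * lam)
  expect_equal(mean(frac), p_true,
               tolerance = 3 * sqrt(p_true * (1 - p_true) / 1600) / p_true)

  expect_error(simulate_detection_session(c(high = 1.2), 0.1, 100, 1),
               "probabilities")
  # 40% catch mix
  expect_equal(sum(s1$trials$condition == "catch"), 48)
})

test_that("Fig. 8 fixture reproduces the printed counts", {
  fx <- make_fixture_fig8_session()
  tab <- table(fx$condition)
  expect_identical(as.integer(tab[c("high", "high_opto", "low", "low_opto",
                                    "opto_only", "sham", "catch")]),
                   c(115L, 123L, 118L, 109L, 119L, 116L, 467L))
  scored <- classify_trial_outcomes(fx)
  expect_identical(sum(scored$outcome == "hit" &
                         scored$condition == "sham"), 44L)
  expect_identical(sum(scored$outcome == "false_alarm"), 156L)
  # deterministic
  expect_identical(fx, make_fixture_fig8_session())
})

test_that("RF response generator peaks on the overlapping stimuli", {
  geom <- rf_stimulus_geometry()
  sim <- simulate_rf_responses(geom, rf = list(ecc = 8, angle = -70,
                                               ecc_sd = 0.8, angle_sd = 8,
                                               gain = 6),
                               n_reps = 15, noise_sd = 0.3, seed = 5)
  res <- classify_rf_modulation(sim$epochs, geom)
  tests <- res$tests
  best_wedge <- tests$stim_id[tests$kind == "wedge"][
    which.max(tests$mean_response[tests$kind == "wedge"])]
  best_ann <- tests$stim_id[tests$kind == "annulus"][
    which.max(tests$mean_response[tests$kind == "annulus"])]
  # RF at (8 deg, -70 deg) sits in wedge_3 (-90..-45) and annulus_4 (7.5..10)
  expect_identical(best_wedge, "wedge_3")
  expect_identical(best_ann, "annulus_4")
  expect_error(simulate_rf_responses(geom[0, ], seed = 1), "empty")
})
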