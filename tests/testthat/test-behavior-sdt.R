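test_that("saccade detector finds simulated saccades accurately", {
  flat <- simulate_eye_trace(NULL, duration = 1, jitter_sd = 0, seed = 1)
  expect_identical(nrow(detect_saccades(flat$eye)), 0L)

  sched <- data.frame(t = c(0.4, 1.3), amplitude = c(8, 3),
                      direction = c(-72.7, 90))
  sim <- simulate_eye_trace(sched, duration = 2, seed = 2)
  det <- detect_saccades(sim$eye)
  expect_identical(nrow(det), 2L)
  expect_lt(max(abs(det$onset - sim$truth$onset)), 0.0035)
  expect_lt(max(abs(det$amplitude - sim$truth$amplitude)), 0.2)
  expect_equal(det$direction[1], -72.7, tolerance = 0.05)

  # two saccades 100 ms apart stay separate events
  close2 <- simulate_eye_trace(data.frame(t = c(0.5, 0.6),
                                          amplitude = c(4, 4),
                                          direction = c(0, 180)),
                               duration = 1.2, seed = 3)
  expect_identical(nrow(detect_saccades(close2$eye)), 2L)

  expect_error(detect_saccades(eye_trace((0:29) / 1000, rep(0, 30),
                                         rep(0, 30), 1000)), "50 ms")
})

test_that("outcome classification follows the hit-window rules", {
  tt <- trial_table(data.frame(
    trial_id = 1:5,
    condition = c("high", "low", "opto_only", "catch", "catch"),
    fixation_on = (0:4) * 2, background_on = (0:4) * 2 + 0.1,
    target_on = c(0.3, 2.3, NA, NA, NA),
    laser_on = c(NA, NA, 4.3, NA, NA),
    response_time = c(0.5, 2.33, NA, 6.5, NA),  # 200 ms, 30 ms, none, FA
    outcome = NA_character_))
  out <- classify_trial_outcomes(tt)
  expect_identical(out$outcome,
                   c("hit", "early", "miss", "false_alarm",
                     "correct_rejection"))
  # partition: every trial got exactly one outcome
  expect_false(any(is.na(out$outcome)))

  broken <- as.data.frame(tt)
  broken$laser_on[3] <- NA
  broken$target_on[3] <- NA
  broken$condition[3] <- "opto_only"
  expect_error(classify_trial_outcomes(broken), "reference onset")
})

test_that("condition rates carry Clopper-Pearson intervals", {
  tt <- trial_table(data.frame(
    trial_id = 1:10, condition = "low",
    fixation_on = (0:9) * 2, background_on = (0:9) * 2 + 0.1,
    target_on = (0:9) * 2 + 0.3, laser_on = NA,
    response_time = NA, outcome = rep("miss", 10)))
  r <- condition_rates(tt)
  expect_equal(r$rate, 0)
  expect_equal(r$ci_lo, 0)
  expect_equal(r$ci_hi, 1 - 0.025^(1 / 10), tolerance = 1e-9)
})

test_that("catch-trial correction reduces to closed-form edge cases", {
  # all catch saccades inside every go window: corrected = raw rate
  go <- rep(0.2, 50)
  catch_in <- c(rep(0.4, 30), rep(NA, 70))  # 0.4 in [0.25, 0.7) always
  r <- corrected_false_alarm_rate(catch_in, go, reps = 200, seed = 1)
  expect_equal(r$rate, 0.3, tolerance = 0.03)

  # all catch saccades outside all windows: corrected = 0
  catch_out <- c(rep(0.1, 30), rep(NA, 70))
  r0 <- corrected_false_alarm_rate(catch_out, go, reps = 50, seed = 1)
  expect_equal(r0$rate, 0)

  # windowing can only remove events
  set.seed(4)
  catch_mix <- ifelse(runif(100) < 0.5, runif(100, 0, 0.8), NA)
  go_mix <- runif(60, 0.15, 0.32)
  rc <- corrected_false_alarm_rate(catch_mix, go_mix, reps = 200, seed = 2)
  expect_lte(rc$rate, mean(!is.na(catch_mix)) + 1e-12)

  expect_error(corrected_false_alarm_rate(catch_mix, numeric(0)),
               "no go trials")
  # literal reading remains available
  rl <- corrected_false_alarm_rate(catch_mix, go_mix, reps = 100, seed = 3,
                                   catch_source = "fa_only")
  expect_lte(rl$rate, mean(!is.na(catch_mix)))
})

test_that("pairwise chi-squared + BH keeps adjusted p monotone", {
  resp <- c(high = 50, low = 50, low_opto = 25, high_opto = 50,
            opto_only = 25, sham = 25, catch = 100)
  tot <- c(high = 100, low = 100, low_opto = 50, high_opto = 100,
           opto_only = 50, sham = 50, catch = 200)
  r <- pairwise_rate_tests(resp, tot)
  expect_true(all(r$p_adj >= r$p_raw - 1e-12))
  expect_true(all(r$p_adj <= 1))
  expect_true(all(r$p_raw > 0.99))   # identical proportions everywhere
  # adjusted p monotone in raw p
  o <- order(r$p_raw)
  expect_true(all(diff(r$p_adj[o]) >= -1e-12))
})

test_that("d' and c satisfy their algebraic identities", {
  r <- dprime_criterion(0.8413, 0.1587)
  expect_equal(r$dprime, 2, tolerance = 1e-3)
  expect_equal(r$c, 0, tolerance = 1e-3)
  for (p in c(0.1, 0.35, 0.77)) {
    expect_equal(dprime_criterion(p, p)$dprime, 0)
    a <- dprime_criterion(0.7, p)
    b <- dprime_criterion(p, 0.7)
    expect_equal(a$dprime, -b$dprime)
    expect_equal(a$c, b$c)
  }
  expect_error(dprime_criterion(1, 0.5), "correction")

  # 1e-9 agreement with an independent inverse-normal oracle
  grid <- seq(0.01, 0.99, by = 0.01)
  z_oracle <- qnorm_oracle(grid)
  for (i in seq(1, 99, by = 7)) {
    r <- dprime_criterion(grid[i], grid[100 - i])
    expect_equal(r$dprime, z_oracle[i] - z_oracle[100 - i],
                 tolerance = 1e-9)
  }
})

test_that("bootstrap SDT behaves under null, separation, and scaling", {
  a <- bootstrap_sdt(60, 40, 30, 70, B = 4000, seed = 1)
  b <- bootstrap_sdt(60, 40, 30, 70, B = 4000, seed = 2)
  nullc <- sdt_contrast(a, b)
  expect_gt(nullc$p[1], 0.2)
  expect_true(a$dprime_ci[1] <= a$dprime && a$dprime <= a$dprime_ci[2])

  big <- bootstrap_sdt(95, 5, 50, 50, B = 10000, seed = 3)
  ref <- bootstrap_sdt(50, 50, 50, 50, B = 10000, seed = 4)
  sep <- sdt_contrast(ref, big)
  expect_equal(sep$p[1], 1e-4)

  # CI width shrinks roughly as 1/sqrt(n)
  small <- bootstrap_sdt(60, 40, 30, 70, B = 6000, seed = 5)
  x4 <- bootstrap_sdt(240, 160, 120, 280, B = 6000, seed = 6)
  ratio <- diff(small$dprime_ci) / diff(x4$dprime_ci)
  expect_equal(ratio, 2, tolerance = 0.3)

  expect_error(bootstrap_sdt(10, 10, 10, 10, B = 50), "at least 100")
  expect_error(bootstrap_sdt(0, 10, 5, 10), "positive")
})

test_that("simulated sessions give unbiased condition rates", {
  hp <- c(high = 0.9, low = 0.55, low_opto = 0.8, sham = 0.1)
  errs <- matrix(NA_real_, 8, length(hp))
  for (s in 1:8) {
    sim <- simulate_detection_session(hp, lambda = 0, n_trials = 1400,
                                      seed = s)
    scored <- classify_trial_outcomes(sim$trials)
    cr <- condition_rates(scored)
    errs[s, ] <- cr$rate[match(names(hp), cr$condition)] - hp
  }
  expect_lt(max(abs(colMeans(errs))), 0.02)
})

test_that("behavior_report assembles every block", {
  fx <- make_fixture_fig8_session()
  scored <- classify_trial_outcomes(fx)
  rep <- behavior_report(scored, seed = 1, B = 500)
  expect_s3_class(rep$rates, "condition_rates")
  expect_equal(nrow(rep$pairwise), 5)
  expect_true(rep$corrected_fa$rate <= 156 / 467 + 1e-12)
  expect_true(!is.null(rep$sdt$contrast))
})
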