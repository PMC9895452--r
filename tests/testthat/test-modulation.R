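null_tensor <- function(n_trials = 20, nch = 1, n = 900, sd = 1,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(list(data = array(rnorm(n_trials * nch * n, sd = sd),
                              c(n_trials, nch, n)),
                 window = c(-0.25, 0.65), rate = 1000,
                 events = seq_len(n_trials)),
            class = "trial_tensor")
}

add_step <- function(tensor, z_units, from = 0) {
  avg_sd <- 1 / sqrt(dim(tensor$data)[1])
  idx <- tensor_time(tensor) >= from
  tensor$data[, , idx] <- tensor$data[, , idx] + z_units * avg_sd
  tensor
}

test_that("baseline z-scoring behaves under construction and affine maps", {
  tens <- add_step(null_tensor(seed = 11), 5)
  z <- zscore_to_baseline(tens, c(-0.25, 0))
  stim <- tensor_time(tens) >= 0
  expect_equal(mean(z[1, stim]), 5, tolerance = 0.8)
  expect_lt(max(abs(z[1, !stim])), 4)

  # affine invariance
  tens2 <- tens
  tens2$data <- tens2$data * 7.3 + 42
  expect_equal(zscore_to_baseline(tens2, c(-0.25, 0)), z, tolerance = 1e-9)

  const <- null_tensor(sd = 0)
  expect_error(zscore_to_baseline(const, c(-0.25, 0)), "zero baseline")
})

test_that("MUA modulation conjunction flags steps and spares nulls", {
  set.seed(21)
  tens <- null_tensor()
  expect_false(classify_mua_modulation(tens)$modulated[1])
  expect_true(classify_mua_modulation(add_step(null_tensor(), 10))$modulated[1])
  expect_error(classify_mua_modulation(tens, c(-0.25, 0), c(-0.1, 0.65)),
               "disjoint")
  # the per-trial KS variant is also available
  r <- classify_mua_modulation(add_step(null_tensor(), 10),
                               ks_units = "trials")
  expect_true(r$modulated[1])
})

test_that("SUA modulation finds rate changes and calibrates near alpha", {
  set.seed(5)
  mk_unit <- function(rate, dur = 40) {
    n <- rpois(1, rate * dur)
    spike_cluster("u", sort(runif(n, 0, dur)))
  }
  ev_stim <- seq(1, 18, by = 2)
  ev_ctrl <- seq(21, 38, by = 2)
  # 5x rate increase during stimulation windows
  st <- sort(c(runif(100, 0, 40),
               as.vector(outer(runif(30, 0, 0.25), ev_stim, `+`))))
  r <- classify_sua_modulation(spike_cluster("u", st), ev_stim, ev_ctrl)
  expect_true(r$modulated)

  # zero spikes: no error, not modulated
  r0 <- classify_sua_modulation(spike_cluster("u", numeric(0)),
                                ev_stim, ev_ctrl)
  expect_false(r0$modulated)

  expect_error(classify_sua_modulation(mk_unit(5), numeric(0), ev_ctrl),
               "empty")

  # type-I calibration: identical Poisson rates in both groups
  fp <- 0
  n_rep <- 150
  for (i in seq_len(n_rep)) {
    u <- mk_unit(8)
    fp <- fp + classify_sua_modulation(u, ev_stim, ev_ctrl)$modulated
  }
  # conjunction with the z criterion keeps the rate at or below alpha
  expect_lte(fp / n_rep, 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("PSTH matches a Poisson oracle and preserves counts", {
  set.seed(31)
  r_true <- 40
  dur <- 60
  st <- sort(runif(rpois(1, r_true * dur), 0, dur))
  events <- seq(5, 55, by = 5)
  psth <- compute_psth(st, events, c(-0.5, 0.5), sigma = 0.01)
  expect_equal(mean(psth$rate), r_true,
               tolerance = 3 * mean(psth$sem) / r_true + 0.05)
  # unit-integral kernel preserves total count (interior window)
  n_in <- sum(vapply(events, function(e)
    sum(st >= e - 0.5 & st < e + 0.5), numeric(1)))
  expect_equal(sum(psth$rate) * 0.001 * length(events), n_in,
               tolerance = 0.01)
  expect_true(all(compute_psth(numeric(0), events, c(0, 0.2))$rate == 0))
})

test_that("autocorrelogram is symmetric, normalized, and finds periodicity", {
  # regular 100 Hz train: peaks at +/-10 ms with value 1
  st <- seq(0, 10, by = 0.01)
  acg <- autocorrelogram(st)
  expect_equal(acg$acg, rev(acg$acg))      # exact symmetry
  expect_equal(max(acg$acg), 1)
  pk <- acg$lag[acg$acg == 1]
  expect_equal(sort(abs(pk))[1], 0.010, tolerance = 0.02)  # half-bin centering
  expect_error(autocorrelogram(1.0), "at least 2")
  expect_error(autocorrelogram(c(2, 1)), "sorted")

  # 80 Hz-entrained unit: global off-center peak at 1/80 = 12.5 ms
  st <- simulate_entrained_train(80, 120, seed = 3)
  acg <- autocorrelogram(st)
  expect_equal(abs(acg$lag[which.max(acg$acg)]), 0.0125,
               tolerance = 0.0005 / 0.0125)

  # Poisson train is flat (1e5 spikes)
  set.seed(41)
  st <- sort(runif(1e5, 0, 1000))
  acg <- autocorrelogram(st)
  inner <- acg$acg[abs(acg$lag) > 0.001]
  expect_lt(max(inner) / min(inner), 1.5)
})

test_that("orientation tuning fit recovers planted parameters", {
  th <- seq(22.5, 180, by = 22.5)
  flat <- fit_orientation_tuning(th, rep(10, 8))
  expect_true(flat$kappa < 1e-6 || flat$a < 1e-6)

  set.seed(51)
  truth <- 10 + 8 * exp(2 * (cos(2 * (th - 45) * pi / 180) - 1))
  fit <- fit_orientation_tuning(th, truth + rnorm(8, sd = 0.2))
  expect_lt(min(abs(fit$theta_pref - 45), 180 - abs(fit$theta_pref - 45)), 5)
  expect_true(fit$theta_pref >= 0 && fit$theta_pref < 180)
  expect_error(fit_orientation_tuning(c(0, 45, 90), c(1, 2, 1)),
               "4 distinct")
})

test_that("firing-rate stability trims edges and is flat for Poisson", {
  set.seed(61)
  st <- sort(runif(6000, 0, 120))
  out <- firing_rate_stability(st, c(0, 120))
  expect_gte(min(out$time), 5)
  expect_lte(max(out$time), 115)
  expect_lt(max(abs(out$rate - 50)) / 50, 0.25)
  expect_lt(sd(out$rate) / mean(out$rate), 0.10)
  expect_true(all(firing_rate_stability(numeric(0), c(0, 30))$rate == 0))
  expect_error(firing_rate_stability(st, c(0, 15)), "20 s")
})
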