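# Ground-truth generators for every input the pipeline consumes. The
# defaults mirror the recorded sessions' stated structure: 25 kHz traces on
# 32-site shanks at 25 um pitch, 1 kHz eye traces, sinusoidal laser
# entrainment, a detection session with 40% catch trials and a
# time-homogeneous false-alarm hazard, and the printed trial counts of the
# behavioral session.

#' Optogenetic laser power waveform
#'
#' Sinusoidal drive of amplitude `peak/2` about `peak/2` (trough 0 mW,
#' crest `peak`), starting at its trough when `phase = 0`; `freq = 0`
#' renders a constant plateau at `peak`. Both cases are enveloped by
#' half-sine tapers with 5 ms trough-to-peak time so power starts and ends
#' at exactly 0 mW (no sharp transients).
#'
#' @param freq modulation frequency, Hz (0 for a square pulse).
#' @param duration s.
#' @param peak mW.
#' @param phase radians.
#' @param rate waveform sample rate, Hz.
#' @param taper trough-to-peak taper time, s.
#' @return list of class `laser_waveform`: `samples` (mW), `rate`, `freq`,
#'   `peak`, `phase`, `taper`.
#' @export
make_laser_waveform <- function(freq, duration, peak, phase = 0,
                                rate = 25000, taper = 0.005) {
  stopifnot(duration > 0, freq >= 0, peak > 0)
  if (duration < 2 * taper)
    stop("duration (", duration, " s) shorter than the two ", taper,
         " s tapers")
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / (n - 1) * duration
  base <- if (freq > 0) peak / 2 * (1 - cos(2 * pi * freq * t + phase))
          else rep(peak, n)
  env <- rep(1, n)
  ramp_up <- t < taper
  env[ramp_up] <- 0.5 * (1 - cos(pi * t[ramp_up] / taper))
  ramp_dn <- t > duration - taper
  env[ramp_dn] <- 0.5 * (1 - cos(pi * (duration - t[ramp_dn]) / taper))
  structure(list(samples = base * env, rate = rate, freq = freq,
                 peak = peak, phase = phase, taper = taper),
            class = "laser_waveform")
}

#' Recording-simulator configuration
#'
#' Defaults describe the recorded preparation: one 32-site shank at 25 um
#' pitch sampled at 25 kHz, ~10 uV white noise with a 1/f component.
#'
#' @param ... overrides of `n_shanks`, `sites_per_shank`, `pitch_um`,
#'   `rate`, `duration`, `noise_sd`, `pink_sd`, `units`, `visual_onsets`,
#'   `laser_onsets`, `laser`, `visual_tau`, `visual_dur`.
#' @return configuration list for [simulate_recording()].
#' @export
default_sim_config <- function(...) {
  cfg <- list(n_shanks = 1L, sites_per_shank = 32L, pitch_um = 25,
              rate = 25000, duration = 2, noise_sd = 10, pink_sd = 3,
              units = NULL, visual_onsets = numeric(0),
              laser_onsets = numeric(0), laser = NULL,
              visual_tau = 0.05, visual_dur = 0.65)
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

# Inhomogeneous Poisson sampling by thinning on a 1 ms grid, with a 2 ms
# absolute refractory period.
sample_spikes <- function(rate_fn, duration, refractory = 0.002) {
  grid <- seq(0, duration, by = 0.001)
  r <- rate_fn(grid)
  rmax <- max(r, 1e-9)
  n_cand <- stats::rpois(1, rmax * duration)
  if (n_cand == 0) return(numeric(0))
  cand <- sort(stats::runif(n_cand, 0, duration))
  keep <- stats::runif(n_cand) < rate_fn(cand) / rmax
  st <- cand[keep]
  if (length(st) > 1) {
    out <- st[1]
    for (s in st[-1]) if (s - out[length(out)] >= refractory) out <- c(out, s)
    st <- out
  }
  st
}

#' Simulate a multichannel extracellular recording
#'
#' Gaussian plus 1/f noise on a 32-site, 25 um-pitch shank layout, with
#' biphasic spike waveforms (amplitude decaying as `exp(-d / 40 um)` across
#' sites) inserted at ground-truth times. Units flagged `visual` fire with
#' an alpha-kernel rate after each visual onset; `opto` units fire with
#' rate proportional to the laser waveform; `suppressed` units drop their
#' baseline rate during the laser.
#'
#' @param cfg list from `default_sim_config()`-style arguments; `units` is
#'   a data.frame with `shank`, `depth_um`, `kind`
#'   (`none`/`visual`/`opto`/`suppressed`), `baseline_rate`, `peak_rate`,
#'   `amplitude_uV`, and optional `width_ms`.
#' @param seed RNG seed.
#' @return list: `block` ([recording_block()]), `truth` (per-unit spike
#'   times, kinds, entrainment frequency, per-unit channel weights).
#' @export
simulate_recording <- function(cfg = default_sim_config(), seed = 1) {
  nch <- cfg$n_shanks * cfg$sites_per_shank
  nt <- round(cfg$duration * cfg$rate)
  cmap <- data.frame(
    channel = seq_len(nch),
    shank = rep(seq_len(cfg$n_shanks), each = cfg$sites_per_shank),
    site = rep(seq_len(cfg$sites_per_shank) - 1L, cfg$n_shanks),
    depth_um = rep((seq_len(cfg$sites_per_shank) - 1) * cfg$pitch_um,
                   cfg$n_shanks))
  span <- range(cmap$depth_um)
  units <- cfg$units
  if (!is.null(units) && nrow(units)) {
    if (any(units$depth_um < span[1] | units$depth_um > span[2]))
      stop("unit depth outside probe span [", span[1], ", ", span[2], "] um")
  }
  truth <- list(units = list())
  trace <- with_rng_stream(seed, "recording_noise", {
    m <- matrix(stats::rnorm(nch * nt, sd = cfg$noise_sd), nch, nt)
    if (cfg$pink_sd > 0 && nt > 4) {
      for (ch in seq_len(nch)) {
        w <- stats::rnorm(nt)
        W <- stats::fft(w)
        f <- c(1, seq_len(nt - 1))
        f <- pmin(f, nt - f + 1)
        W <- W / sqrt(f)
        p <- Re(stats::fft(W, inverse = TRUE)) / nt
        m[ch, ] <- m[ch, ] + cfg$pink_sd * p / stats::sd(p)
      }
    }
    m
  })
  if (!is.null(units) && nrow(units)) {
    lw <- cfg$laser
    for (u in seq_len(nrow(units))) {
      kind <- units$kind[u]
      base <- units$baseline_rate[u]
      peakr <- units$peak_rate[u]
      rate_fn <- switch(kind,
        none = function(tt) rep(base, length(tt)),
        visual = function(tt) {
          r <- rep(base, length(tt))
          for (on in cfg$visual_onsets) {
            rel <- tt - on
            in_w <- rel >= 0 & rel < cfg$visual_dur
            r[in_w] <- r[in_w] + peakr * (rel[in_w] / cfg$visual_tau) *
              exp(1 - rel[in_w] / cfg$visual_tau)
          }
          r
        },
        opto = function(tt) {
          r <- rep(base, length(tt))
          if (!is.null(lw)) for (on in cfg$laser_onsets) {
            rel <- tt - on
            idx <- rel >= 0 & rel < length(lw$samples) / lw$rate
            si <- pmin(length(lw$samples),
                       floor(rel[idx] * lw$rate) + 1)
            r[idx] <- r[idx] + peakr * lw$samples[si] / lw$peak
          }
          r
        },
        suppressed = function(tt) {
          r <- rep(base, length(tt))
          if (!is.null(lw)) for (on in cfg$laser_onsets) {
            idx <- tt >= on & tt < on + length(lw$samples) / lw$rate
            r[idx] <- r[idx] * 0.1
          }
          r
        },
        stop("unknown unit kind: ", kind))
      st <- with_rng_stream(seed, paste0("unit_", u),
                            sample_spikes(rate_fn, cfg$duration))
      width_ms <- if (!is.null(units$width_ms)) units$width_ms[u] else 0.5
      tmpl_t <- (seq_len(41) - 16) / cfg$rate
      tmpl <- biphasic_template(tmpl_t, width_ms / 1000) *
        units$amplitude_uV[u]
      d <- abs(cmap$depth_um - units$depth_um[u])
      wts <- exp(-d / 40) * (cmap$shank == units$shank[u])
      idx <- as.integer(round(st * cfg$rate)) - 15L
      trace <- cpp_insert_spikes(trace, idx, tmpl, wts)
      truth$units[[u]] <- list(spike_times = st, kind = kind,
                               entrain_freq = if (kind == "opto" &&
                                                  !is.null(lw)) lw$freq
                                              else NA_real_,
                               depth_um = units$depth_um[u],
                               shank = units$shank[u],
                               channel_weights = wts)
    }
  }
  list(block = recording_block(trace, cfg$rate, cmap), truth = truth)
}

#' Simulate a tightly entrained spike train
#'
#' Spikes lock to the crests of a sinusoidal optogenetic drive with sub-
#' millisecond Gaussian jitter: per cycle a spike occurs with probability
#' `p_spike` at the crest time plus jitter, with an absolute refractory
#' period. The locking phase additionally diffuses slowly across cycles
#' (`phase_walk_sd` per cycle), so autocorrelogram peaks at multiples of
#' the period decay with lag — the regime implied by a sharp, dominant
#' first peak at the stimulation period (a rate merely proportional to the
#' waveform cannot localize the peak below the width of a crest).
#'
#' @param freq drive frequency, Hz.
#' @param duration s.
#' @param p_spike per-cycle spike probability.
#' @param jitter_sd per-spike locking jitter SD, s.
#' @param phase_walk_sd per-cycle SD of the phase random walk, s.
#' @param refractory s.
#' @param seed RNG seed.
#' @return sorted spike times, s.
#' @export
simulate_entrained_train <- function(freq, duration, p_spike = 0.6,
                                     jitter_sd = 2e-4,
                                     phase_walk_sd = 4e-4,
                                     refractory = 0.002, seed = 1) {
  stopifnot(freq > 0, duration > 0, p_spike > 0, p_spike <= 1)
  with_rng_stream(seed, "entrained", {
    crests <- seq(1 / (2 * freq), duration, by = 1 / freq)
    drift <- cumsum(stats::rnorm(length(crests), 0, phase_walk_sd))
    fire <- stats::runif(length(crests)) < p_spike
    st <- sort(crests[fire] + drift[fire] +
                 stats::rnorm(sum(fire), 0, jitter_sd))
    st <- st[st >= 0 & st < duration]
    if (length(st) > 1) {
      out <- st[1]
      for (s in st[-1]) if (s - out[length(out)] >= refractory)
        out <- c(out, s)
      st <- out
    }
    st
  })
}

#' Simulate a 1 kHz eye trace with velocity-profiled saccades
#'
#' Mean-reverting (Ornstein-Uhlenbeck) fixational jitter plus saccades
#' whose speed follows a Gaussian pulse; for amplitudes of at least 0.5
#' degrees the peak speed exceeds the 50 deg/s detection threshold. The
#' ground-truth onset is the first sample of the velocity pulse.
#'
#' @param saccades data.frame with `t` (onset, s), `amplitude` (deg),
#'   `direction` (deg CCW from +x).
#' @param duration s.
#' @param jitter_sd fixational jitter SD, deg.
#' @param jitter_tau OU time constant, s.
#' @param blinks optional data.frame with `t`, `duration` of blinks.
#' @param rate Hz.
#' @param seed RNG seed.
#' @return list: `eye` ([eye_trace()]), `truth` (onsets, offsets,
#'   amplitudes, directions).
#' @export
simulate_eye_trace <- function(saccades = NULL, duration = 2,
                               jitter_sd = 0.05, jitter_tau = 0.05,
                               blinks = NULL, rate = 1000, seed = 1) {
  n <- round(duration * rate)
  dt <- 1 / rate
  tt <- (seq_len(n) - 1) * dt
  # main-sequence-like width; pulse truncated at +/-2 sigma so speed rises
  # past the 50 deg/s detection threshold within a few samples of onset
  sigma_s <- function(a) 0.003 + 0.0005 * a
  if (!is.null(saccades) && nrow(saccades) > 1) {
    o <- order(saccades$t)
    saccades <- saccades[o, ]
    span_end <- saccades$t + 4 * sigma_s(saccades$amplitude)
    if (any(saccades$t[-1] < span_end[-nrow(saccades)]))
      stop("scheduled saccades overlap")
  }
  vx <- vy <- numeric(n)
  truth <- NULL
  if (!is.null(saccades) && nrow(saccades)) {
    rows <- lapply(seq_len(nrow(saccades)), function(i) {
      a <- saccades$amplitude[i]
      s <- sigma_s(a)
      t0 <- saccades$t[i]
      prof <- stats::dnorm(tt, t0 + 2 * s, s)
      prof[tt < t0 | tt > t0 + 4 * s] <- 0
      prof <- prof / (sum(prof) * dt) * a   # exact displacement
      th <- saccades$direction[i] * pi / 180
      vx <<- vx + prof * cos(th)
      vy <<- vy + prof * sin(th)
      data.frame(onset = t0, offset = t0 + 4 * s, amplitude = a,
                 direction = saccades$direction[i],
                 peak_speed = max(prof))
    })
    truth <- do.call(rbind, rows)
  }
  jit <- with_rng_stream(seed, "eye_jitter", {
    ou <- function() {
      z <- numeric(n)
      if (jitter_sd > 0) {
        g <- stats::rnorm(n)
        k <- dt / jitter_tau
        for (i in 2:n) z[i] <- z[i - 1] * (1 - k) +
            jitter_sd * sqrt(2 * k) * g[i]
      }
      z
    }
    list(x = ou(), y = ou())
  })
  x <- cumsum(vx) * dt + jit$x
  y <- cumsum(vy) * dt + jit$y
  blink <- rep(FALSE, n)
  if (!is.null(blinks) && nrow(blinks)) {
    for (i in seq_len(nrow(blinks))) {
      idx <- tt >= blinks$t[i] & tt < blinks$t[i] + blinks$duration[i]
      blink[idx] <- TRUE
      y[idx] <- y[idx] - 30   # lid-closure excursion, masked
    }
  }
  list(eye = eye_trace(tt, x, y, rate, blink), truth = truth)
}

#' Simulate a detection-task session
#'
#' 40% catch trials; go-trial target/laser onset uniform 150-320 ms after
#' background onset; per-condition hit probabilities with log-normal
#' latency (median 0.25 s, sigma_log 0.3, truncated to the 50-500 ms hit
#' window); false alarms from a homogeneous Poisson hazard `lambda`
#' starting at background onset. Outcomes are left unscored — scoring is
#' the pipeline's job — but the ground truth is returned.
#'
#' @param hit_prob named vector of hit probabilities per go condition.
#' @param lambda false-alarm hazard, events/s.
#' @param n_trials total trial count.
#' @param seed RNG seed.
#' @param cfg [analysis_config()].
#' @return list: `trials` ([trial_table()]), `truth` (per-trial latent
#'   response type and times, plus `hit_prob`, `lambda`).
#' @export
simulate_detection_session <- function(hit_prob = c(high = 0.95,
                                                    high_opto = 0.95,
                                                    low = 0.55,
                                                    low_opto = 0.8,
                                                    opto_only = 0.2,
                                                    sham = 0.05),
                                       lambda = 0.5, n_trials = 500,
                                       seed = 1, cfg = analysis_config()) {
  if (any(hit_prob < 0 | hit_prob > 1))
    stop("hit probabilities must lie in [0, 1]")
  stopifnot(lambda >= 0)
  go_conds <- names(hit_prob)
  with_rng_stream(seed, "session", {
    n_catch <- round(cfg$catch_fraction * n_trials)
    conds <- sample(c(rep("catch", n_catch),
                      go_conds[1 + (seq_len(n_trials - n_catch) - 1) %%
                                 length(go_conds)]))
    fixation_on <- (seq_len(n_trials) - 1) * 2
    background_on <- fixation_on + stats::runif(n_trials, 0.10, 0.15)
    onset_lat <- stats::runif(n_trials, 0.15, 0.32)
    target_on <- laser_on <- response_time <- rep(NA_real_, n_trials)
    truth_type <- character(n_trials)
    truth_hit_t <- truth_fa_t <- rep(NA_real_, n_trials)
    win <- cfg$hit_window
    for (i in seq_len(n_trials)) {
      cond <- conds[i]
      trial_end <- if (cond == "catch")
        background_on[i] + cfg$catch_fixation_s
      else background_on[i] + onset_lat[i] + win[2]
      # latent false alarm from the homogeneous hazard
      if (lambda > 0) {
        fa <- background_on[i] + stats::rexp(1, lambda)
        if (fa < trial_end) truth_fa_t[i] <- fa
      }
      if (cond != "catch") {
        on <- background_on[i] + onset_lat[i]
        if (cond %in% c("high", "low")) target_on[i] <- on
        else if (cond %in% c("opto_only", "sham")) laser_on[i] <- on
        else { target_on[i] <- on; laser_on[i] <- on + 1e-6 }
        if (stats::runif(1) < hit_prob[cond]) {
          repeat {
            lat <- stats::rlnorm(1, log(0.25), 0.3)
            if (lat >= win[1] && lat < win[2]) break
          }
          truth_hit_t[i] <- on + lat
        }
      }
      cand <- c(truth_hit_t[i], truth_fa_t[i])
      cand <- cand[!is.na(cand) & cand < trial_end]
      if (length(cand)) response_time[i] <- min(cand)
      truth_type[i] <-
        if (is.na(response_time[i])) "none"
        else if (!is.na(truth_hit_t[i]) &&
                 response_time[i] == truth_hit_t[i]) "hit"
        else "fa"
    }
    trials <- trial_table(data.frame(
      trial_id = seq_len(n_trials), condition = conds,
      fixation_on = fixation_on, background_on = background_on,
      target_on = target_on, laser_on = laser_on,
      response_time = response_time, outcome = NA_character_))
    list(trials = trials,
         truth = list(hit_prob = hit_prob, lambda = lambda,
                      type = truth_type, hit_time = truth_hit_t,
                      fa_time = truth_fa_t))
  })
}

#' Deterministic behavioral-session fixture with the printed trial counts
#'
#' Reconstructs the published session: per-condition totals 115 (high),
#' 123 (high+opto), 118 (low), 109 (low+opto), 119 (opto only), 116
#' (sham), 467 (catch), with responder counts 108, 109, 66, 89, 53, 44
#' hits and 156 catch trials with a saccade (the printed corrected
#' false-alarm rate 33.4% times 467, rounded). Hit latencies sit inside
#' the 50-500 ms window; catch saccade times spread evenly over the 800 ms
#' fixation requirement.
#'
#' @return unscored [trial_table()] (score with
#'   [classify_trial_outcomes()]).
#' @export
make_fixture_fig8_session <- function() {
  totals <- c(high = 115, high_opto = 123, low = 118, low_opto = 109,
              opto_only = 119, sham = 116, catch = 467)
  responders <- c(high = 108, high_opto = 109, low = 66, low_opto = 89,
                  opto_only = 53, sham = 44, catch = 156)
  cond <- rep(names(totals), totals)
  j <- sequence(totals)
  k <- responders[cond]
  n_all <- length(cond)
  fix_on <- (seq_len(n_all) - 1) * 2
  bg_on <- fix_on + 0.12
  on <- bg_on + 0.2
  is_catch <- cond == "catch"
  is_vis <- cond %in% c("high", "low", "high_opto", "low_opto")
  is_laser <- cond %in% c("opto_only", "sham", "high_opto", "low_opto")
  target_on <- ifelse(is_vis, on, NA_real_)
  laser_on <- ifelse(is_laser,
                     on + ifelse(is_vis, 1e-6, 0), NA_real_)
  resp <- rep(NA_real_, n_all)
  hit <- !is_catch & j <= k
  resp[hit] <- on[hit] + 0.15 + 0.2 * (j[hit] - 0.5) / k[hit]
  fa <- is_catch & j <= k
  resp[fa] <- bg_on[fa] + 0.05 + 0.75 * (j[fa] - 0.5) / k[fa]
  trial_table(data.frame(trial_id = seq_len(n_all), condition = cond,
                         fixation_on = fix_on, background_on = bg_on,
                         target_on = target_on, laser_on = laser_on,
                         response_time = resp, outcome = NA_character_))
}

#' Default wedge/annulus stimulus geometry for RF mapping
#'
#' @param n_wedges wedges tiling the full polar angle.
#' @param n_annuli annuli tiling eccentricity up to `ecc_max`.
#' @param ecc_max outer eccentricity, degrees.
#' @return geometry data.frame (`stim_id`, `kind`, `lo`, `hi`).
#' @export
rf_stimulus_geometry <- function(n_wedges = 8, n_annuli = 6, ecc_max = 15) {
  wedge_edges <- seq(-180, 180, length.out = n_wedges + 1)
  ann_edges <- seq(0, ecc_max, length.out = n_annuli + 1)
  rbind(
    data.frame(stim_id = paste0("wedge_", seq_len(n_wedges)),
               kind = "wedge", lo = wedge_edges[-(n_wedges + 1)],
               hi = wedge_edges[-1]),
    data.frame(stim_id = paste0("annulus_", seq_len(n_annuli)),
               kind = "annulus", lo = ann_edges[-(n_annuli + 1)],
               hi = ann_edges[-1]))
}

#' Simulate epoched MUA responses to RF-mapping stimuli
#'
#' Response amplitude is proportional to the overlap between the stimulus
#' region and a Gaussian receptive field in (eccentricity, polar angle),
#' with additive Gaussian noise; the true RF is returned.
#'
#' @param geometry from [rf_stimulus_geometry()].
#' @param rf list: `ecc`, `angle` (deg), `ecc_sd`, `angle_sd`, `gain`
#'   (response amplitude). `gain = 0` gives a flat (no-RF) site.
#' @param n_reps presentations per stimulus.
#' @param noise_sd additive noise SD.
#' @param seed RNG seed.
#' @param cfg [analysis_config()].
#' @return list: `epochs` (`rf_epochs`), `geometry`, `truth` (the RF).
#' @export
simulate_rf_responses <- function(geometry = rf_stimulus_geometry(),
                                  rf = list(ecc = 8, angle = -70,
                                            ecc_sd = 2, angle_sd = 20,
                                            gain = 5),
                                  n_reps = 20, noise_sd = 1, seed = 1,
                                  cfg = analysis_config()) {
  if (!nrow(geometry)) stop("empty stimulus set")
  win <- cfg$rf_epoch
  nt <- round(diff(win) * 1000)
  tt <- win[1] + (seq_len(nt) - 1) / 1000
  shape <- ifelse(tt >= 0.03 & tt < 0.15,
                  sin(pi * (tt - 0.03) / 0.12), 0)
  overlap <- function(row) {
    if (row$kind == "wedge")
      stats::pnorm(row$hi, rf$angle, rf$angle_sd) -
        stats::pnorm(row$lo, rf$angle, rf$angle_sd)
    else
      stats::pnorm(row$hi, rf$ecc, rf$ecc_sd) -
        stats::pnorm(row$lo, rf$ecc, rf$ecc_sd)
  }
  with_rng_stream(seed, "rf_responses", {
    n_stim <- nrow(geometry)
    dat <- matrix(0, n_stim * n_reps, nt)
    sid <- character(n_stim * n_reps)
    k <- 0
    for (s in seq_len(n_stim)) {
      amp <- rf$gain * overlap(geometry[s, ])
      for (rep_i in seq_len(n_reps)) {
        k <- k + 1
        dat[k, ] <- stats::rnorm(nt, sd = noise_sd) + amp * shape
        sid[k] <- geometry$stim_id[s]
      }
    }
    ord <- sample(k)   # interleave presentations
    epochs <- structure(list(data = dat[ord, , drop = FALSE],
                             stim_id = sid[ord],
                             onset = seq_len(k) * 0.5, time = tt),
                        class = "rf_epochs")
    list(epochs = epochs, geometry = geometry, truth = rf)
  })
}
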