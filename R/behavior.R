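# Detection-task scoring and inference: saccade detection from 1 kHz eye
# traces, outcome classification, per-condition saccade rates with
# Clopper-Pearson intervals, the resampling correction for the longer catch
# trials, pairwise Yates chi-squared tests with Benjamini-Hochberg
# adjustment, and signal detection theory (d', c) with bootstrap inference.

#' Detect saccades by velocity threshold
#'
#' Position is smoothed with a Gaussian window (sigma = 3 ms), speed is the
#' magnitude of the central-difference velocity, and a saccade is a maximal
#' run of samples exceeding 50 deg/s (runs separated by < 10 ms merged).
#' The endpoint is the per-axis median over the 25 ms after offset; the
#' start point is the median over the 25 ms before onset; amplitude and
#' direction derive from those two fixes. Blink samples never contribute
#' to a saccade.
#'
#' @param eye [eye_trace()] at 1 kHz.
#' @param cfg [analysis_config()].
#' @return data.frame, one row per saccade: `onset`, `offset` (s),
#'   `x_end`, `y_end`, `amplitude` (deg), `direction` (deg, CCW from +x),
#'   `peak_speed`, `endpoint_defined`.
#' @export
detect_saccades <- function(eye, cfg = analysis_config()) {
  n <- length(eye$t)
  if (n < 0.05 * eye$rate) stop("trace shorter than 50 ms")
  dt <- 1 / eye$rate
  k <- gauss_kernel(cfg$saccade_smooth_sigma, dt)
  half <- (length(k) - 1) / 2
  smooth1 <- function(v) {
    # reflect-pad so edges keep unit kernel mass
    vp <- c(rev(v[seq_len(half) + 1]), v, rev(v[n - seq_len(half)]))
    stats::convolve(vp, rev(k), type = "open")[(2 * half + 1):(2 * half + n)]
  }
  xs <- smooth1(eye$x)
  ys <- smooth1(eye$y)
  vx <- c(0, (xs[-(1:2)] - xs[1:(n - 2)]) / (2 * dt), 0)
  vy <- c(0, (ys[-(1:2)] - ys[1:(n - 2)]) / (2 * dt), 0)
  speed <- sqrt(vx^2 + vy^2)
  fast <- speed > cfg$saccade_velocity_threshold & !eye$blink
  if (!any(fast))
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      x_end = numeric(0), y_end = numeric(0),
                      amplitude = numeric(0), direction = numeric(0),
                      peak_speed = numeric(0),
                      endpoint_defined = logical(0)))
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by < merge gap
  gap <- round(cfg$saccade_merge_gap * eye$rate)
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start[i] - merged$end[nrow(merged)] < gap)
      merged$end[nrow(merged)] <- runs$end[i]
    else merged <- rbind(merged, runs[i, ])
  }
  epw <- round(cfg$saccade_endpoint_window * eye$rate)
  rows <- lapply(seq_len(nrow(merged)), function(i) {
    s <- merged$start[i]; e <- merged$end[i]
    post <- seq(e + 1, min(n, e + epw))
    pre <- seq(max(1, s - epw), max(1, s - 1))
    ok <- e + epw <= n
    xe <- stats::median(eye$x[post]); ye <- stats::median(eye$y[post])
    x0 <- stats::median(eye$x[pre]);  y0 <- stats::median(eye$y[pre])
    data.frame(onset = eye$t[s], offset = eye$t[e], x_end = xe, y_end = ye,
               amplitude = sqrt((xe - x0)^2 + (ye - y0)^2),
               direction = atan2(ye - y0, xe - x0) * 180 / pi,
               peak_speed = max(speed[s:e]), endpoint_defined = ok)
  })
  do.call(rbind, rows)
}

#' Classify detection-task trial outcomes
#'
#' Go trials (reference onset = `target_on` for visual conditions,
#' `laser_on` for opto-only/sham): a saccade at latency in `[50, 500)` ms
#' is a hit, below 50 ms an early response, none in the window a miss.
#' Catch trials: any saccade within 800 ms of background onset is a false
#' alarm, otherwise a correct rejection.
#'
#' @param trials [trial_table()].
#' @param saccades data.frame from [detect_saccades()], or `NULL` to use
#'   the table's `response_time` column as the saccade onset.
#' @param cfg [analysis_config()].
#' @return trial table with `outcome` and `response_time` (saccade latency
#'   from the reference onset, s) filled in.
#' @export
classify_trial_outcomes <- function(trials, saccades = NULL,
                                    cfg = analysis_config()) {
  trials <- validate_trial_table(trials)
  win <- cfg$hit_window
  for (i in seq_len(nrow(trials))) {
    cond <- trials$condition[i]
    if (!is.na(trials$outcome[i]) && trials$outcome[i] == "excluded") next
    sac_t <- if (is.null(saccades)) trials$response_time[i] else {
      lo <- trials$background_on[i]
      hi <- lo + if (cond == "catch") cfg$catch_fixation_s else 1.0
      cand <- saccades$onset[saccades$onset >= lo & saccades$onset < hi]
      if (length(cand)) cand[1] else NA_real_
    }
    if (cond == "catch") {
      end <- trials$background_on[i] + cfg$catch_fixation_s
      fa <- !is.na(sac_t) && sac_t < end
      trials$outcome[i] <- if (fa) "false_alarm" else "correct_rejection"
      next
    }
    ref <- if (cond %in% c("opto_only", "sham")) trials$laser_on[i]
           else trials$target_on[i]
    if (is.na(ref))
      stop("go trial ", trials$trial_id[i], " (", cond,
           ") lacks its reference onset")
    lat <- sac_t - ref
    trials$outcome[i] <-
      if (is.na(lat) || lat >= win[2]) "miss"
      else if (lat < win[1]) "early"
      else "hit"
    if (!is.na(lat)) trials$response_time[i] <- lat
  }
  trials
}

#' Per-condition saccade rates with 95% Clopper-Pearson intervals
#'
#' Responders are hits for go conditions and false alarms for catch;
#' early/excluded trials do not count toward the totals.
#'
#' @param trials scored [trial_table()].
#' @param conf confidence level.
#' @return data.frame of class `condition_rates`: `condition`,
#'   `responders`, `total`, `rate`, `ci_lo`, `ci_hi`.
#' @export
condition_rates <- function(trials, conf = 0.95) {
  rows <- lapply(intersect(CONDITION_LEVELS, unique(trials$condition)),
                 function(cond) {
    sub <- trials[trials$condition == cond, ]
    if (cond == "catch") {
      k <- sum(sub$outcome == "false_alarm", na.rm = TRUE)
      n <- sum(sub$outcome %in% c("false_alarm", "correct_rejection"))
    } else {
      k <- sum(sub$outcome == "hit", na.rm = TRUE)
      n <- sum(sub$outcome %in% c("hit", "miss"))
    }
    if (n == 0) {
      warning("condition ", cond, " has no scored trials; omitted")
      return(NULL)
    }
    ci <- clopper_pearson(k, n, conf)
    data.frame(condition = cond, responders = k, total = n, rate = k / n,
               ci_lo = ci[1], ci_hi = ci[2])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("condition_rates", "data.frame")
  out
}

clopper_pearson <- function(k, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lo, hi)
}

#' Bias-corrected false-alarm rate for unequal-duration catch trials
#'
#' Catch trials last longer than go trials, so the raw catch saccade rate
#' overestimates the false-alarm rate. Each replicate draws `n_pairs`
#' (catch, go) pairs with replacement; a sampled catch trial with no
#' saccade scores a correct rejection, and one with a saccade at time `t`
#' (relative to background onset) scores a false alarm iff
#' `t` falls in `[T_go + 0.05, T_go + 0.5)` where `T_go` is the paired
#' go trial's reference-onset latency after background onset. Rates and
#' Clopper-Pearson intervals are averaged over replicates.
#'
#' @param catch_saccade_times per catch trial, saccade time relative to
#'   background onset (s), `NA` when the trial had no saccade.
#' @param go_onset_latencies per go trial, reference onset minus background
#'   onset (s).
#' @param n_pairs pairs per replicate; default is the expected catch count
#'   given the go-trial total and the 40% catch fraction.
#' @param reps replicates.
#' @param seed RNG seed.
#' @param catch_source `"all"` (default) samples from all catch trials;
#'   `"fa_only"` follows the literal reading and samples only catch trials
#'   containing a saccade, scaling by the saccade prevalence.
#' @param cfg [analysis_config()].
#' @return list: `rate`, `ci_lo`, `ci_hi` (replicate averages), `n_pairs`,
#'   `reps`.
#' @export
corrected_false_alarm_rate <- function(catch_saccade_times,
                                       go_onset_latencies,
                                       n_pairs = NULL, reps = 1000,
                                       seed = 1,
                                       catch_source = c("all", "fa_only"),
                                       cfg = analysis_config()) {
  catch_source <- match.arg(catch_source)
  if (!length(go_onset_latencies)) stop("no go trials")
  if (!length(catch_saccade_times)) stop("no catch trials")
  if (is.null(n_pairs)) {
    fr <- cfg$catch_fraction
    n_pairs <- round(length(go_onset_latencies) * fr / (1 - fr))
  }
  win <- cfg$hit_window
  has_sac <- !is.na(catch_saccade_times)
  prev <- mean(has_sac)
  rate <- ci_lo <- ci_hi <- numeric(reps)
  with_rng_stream(seed, "fa_correction", {
    for (r in seq_len(reps)) {
      go <- sample(go_onset_latencies, n_pairs, replace = TRUE)
      if (catch_source == "all") {
        ct <- sample(catch_saccade_times, n_pairs, replace = TRUE)
        fa <- sum(!is.na(ct) & ct >= go + win[1] & ct < go + win[2])
      } else {
        if (!any(has_sac)) { fa <- 0 } else {
          ct <- sample(catch_saccade_times[has_sac], n_pairs, replace = TRUE)
          # literal pairing over FA trials; rescale by saccade prevalence
          fa <- sum(ct >= go + win[1] & ct < go + win[2]) * prev
        }
      }
      rate[r] <- fa / n_pairs
      ci <- clopper_pearson(round(fa), n_pairs)
      ci_lo[r] <- ci[1]; ci_hi[r] <- ci[2]
    }
  })
  list(rate = mean(rate), ci_lo = mean(ci_lo), ci_hi = mean(ci_hi),
       n_pairs = n_pairs, reps = reps)
}

#' Pairwise chi-squared tests with Benjamini-Hochberg adjustment
#'
#' Each planned contrast is a 2x2 chi-squared test with Yates continuity
#' correction (two-sided); p-values are then adjusted by the
#' Benjamini-Hochberg step-up procedure across the family.
#'
#' @param responders,totals named integer vectors (per condition).
#' @param family list of length-2 character vectors naming the contrasts;
#'   default is the five planned comparisons of the detection task.
#' @return data.frame: `a`, `b`, `p_raw`, `p_adj`.
#' @export
pairwise_rate_tests <- function(responders, totals, family = NULL) {
  if (is.null(family))
    family <- list(c("high", "low"), c("low", "low_opto"),
                   c("high", "high_opto"), c("opto_only", "catch"),
                   c("sham", "catch"))
  p <- vapply(family, function(cc) {
    k <- responders[cc]; n <- totals[cc]
    if (any(is.na(k)) || any(is.na(n)))
      stop("missing condition in contrast: ", paste(cc, collapse = " vs "))
    m <- rbind(c(k[1], n[1] - k[1]), c(k[2], n[2] - k[2]))
    ex <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(ex < 1))
      warning("expected cell below 1 in contrast ",
              paste(cc, collapse = " vs "))
    suppressWarnings(stats::prop.test(m, correct = TRUE)$p.value)
  }, numeric(1))
  data.frame(a = vapply(family, `[`, "", 1), b = vapply(family, `[`, "", 2),
             p_raw = p, p_adj = stats::p.adjust(p, method = "BH"))
}

#' Full behavioral report for a scored session
#'
#' Convenience wrapper: per-condition rates with binomial CIs, the
#' bias-corrected false-alarm rate, the five planned pairwise chi-squared
#' contrasts with BH adjustment, and the SDT block comparing the
#' low-contrast pair (low vs catch) against the low+opto pair (low+opto vs
#' opto only).
#'
#' @param trials scored [trial_table()] (see [classify_trial_outcomes()]).
#' @param seed RNG seed for the resampling correction and bootstrap.
#' @param B bootstrap replications.
#' @param cfg [analysis_config()].
#' @return list: `rates`, `corrected_fa`, `pairwise`, `sdt` (results and
#'   contrast), suitable for JSON serialization.
#' @export
behavior_report <- function(trials, seed = 1, B = 10000,
                            cfg = analysis_config()) {
  rates <- condition_rates(trials)
  rr <- stats::setNames(rates$responders, rates$condition)
  tt <- stats::setNames(rates$total, rates$condition)
  is_catch <- trials$condition == "catch"
  catch_sac <- trials$response_time[is_catch] -
    trials$background_on[is_catch]
  go <- !is_catch & trials$outcome %in% c("hit", "miss")
  ref <- ifelse(trials$condition %in% c("opto_only", "sham"),
                trials$laser_on, trials$target_on)
  go_lat <- (ref - trials$background_on)[go]
  cfa <- corrected_false_alarm_rate(catch_sac, go_lat,
                                    reps = cfg$fa_resample_reps,
                                    seed = seed, cfg = cfg)
  pw <- pairwise_rate_tests(rr, tt)
  sdt <- NULL
  need <- c("low", "catch", "low_opto", "opto_only")
  if (all(need %in% rates$condition)) {
    s_low <- bootstrap_sdt(rr["low"], tt["low"] - rr["low"],
                           rr["catch"], tt["catch"] - rr["catch"],
                           B = B, seed = seeded_rng(seed, "low_pair"))
    s_opt <- bootstrap_sdt(rr["low_opto"], tt["low_opto"] - rr["low_opto"],
                           rr["opto_only"], tt["opto_only"] - rr["opto_only"],
                           B = B, seed = seeded_rng(seed, "opto_pair"))
    sdt <- list(low_vs_catch = s_low[c("dprime", "c", "dprime_ci", "c_ci")],
                low_opto_vs_opto = s_opt[c("dprime", "c", "dprime_ci",
                                           "c_ci")],
                contrast = sdt_contrast(s_low, s_opt))
  }
  list(rates = rates, corrected_fa = cfa, pairwise = pw, sdt = sdt)
}

#' Sensitivity and criterion from hit and false-alarm rates
#'
#' `d' = Z(HitRate) - Z(FalseAlarmRate)` and
#' `c = -(Z(HitRate) + Z(FalseAlarmRate)) / 2`, with `Z` the inverse
#' Gaussian CDF.
#'
#' @param hit_rate,fa_rate rates strictly inside (0, 1).
#' @return list: `dprime`, `c`.
#' @export
dprime_criterion <- function(hit_rate, fa_rate) {
  if (any(c(hit_rate, fa_rate) <= 0) || any(c(hit_rate, fa_rate) >= 1))
    stop("rates must lie strictly in (0,1); consider the 1/(2N) correction",
         " (`rate_correction = TRUE` in bootstrap_sdt)")
  zh <- stats::qnorm(hit_rate)
  zf <- stats::qnorm(fa_rate)
  list(dprime = zh - zf, c = -(zh + zf) / 2)
}

boot_rates <- function(k, n, B) {
  # resampling a binary indicator vector with replacement is binomial
  r <- stats::rbinom(B, n, k / n) / n
  pmin(pmax(r, 1 / (2 * n)), 1 - 1 / (2 * n))
}

#' Bootstrap inference for d' and c
#'
#' Resamples the hit/miss and false-alarm/correct-rejection indicator
#' vectors with replacement (B = 10,000), recomputing d' and c per
#' replicate; confidence intervals are the 5th and 95th percentiles.
#' Replicate rates of exactly 0 or 1 are clamped by the standard 1/(2N)
#' correction so Z stays finite.
#'
#' @param hits,misses signal-condition counts.
#' @param fa,cr noise-condition counts.
#' @param B replications (>= 100).
#' @param seed RNG seed.
#' @return list of class `sdt_result`: observed `dprime`, `c`, their
#'   bootstrap CI (`dprime_ci`, `c_ci`), replicate draws, and counts.
#' @export
bootstrap_sdt <- function(hits, misses, fa, cr, B = 10000, seed = 1) {
  if (B < 100) stop("B must be at least 100")
  if (min(hits, misses, fa, cr) <= 0)
    stop("all four counts must be positive")
  ns <- hits + misses; nn <- fa + cr
  obs <- dprime_criterion(hits / ns, fa / nn)
  reps <- with_rng_stream(seed, "sdt_boot", {
    h <- boot_rates(hits, ns, B)
    f <- boot_rates(fa, nn, B)
    list(dprime = stats::qnorm(h) - stats::qnorm(f),
         c = -(stats::qnorm(h) + stats::qnorm(f)) / 2)
  })
  structure(list(
    hit_rate = hits / ns, fa_rate = fa / nn,
    dprime = obs$dprime, c = obs$c,
    dprime_ci = stats::quantile(reps$dprime, c(0.05, 0.95), names = FALSE),
    c_ci = stats::quantile(reps$c, c(0.05, 0.95), names = FALSE),
    reps = reps, B = B,
    counts = c(hits = hits, misses = misses, fa = fa, cr = cr)),
    class = "sdt_result")
}

#' Bootstrap contrast between two signal/noise condition pairs
#'
#' Per replicate the difference in d' (and c) between pair B and pair A is
#' drawn; the contrast p-value is, by default, the proportion of replicate
#' differences on the opposite side of zero from the observed difference
#' (one-sided against sign reversal), floored at 1/B. `p_method =
#' "literal"` instead reports the proportion of differences at least as
#' large as the observed one.
#'
#' @param sdt_a,sdt_b [bootstrap_sdt()] results computed with the same `B`
#'   (use different seeds for independence).
#' @param p_method see above.
#' @return data.frame: rows `dprime` and `c` with observed difference,
#'   CI of the difference, and `p`.
#' @export
sdt_contrast <- function(sdt_a, sdt_b,
                         p_method = c("sign_reversal", "literal")) {
  p_method <- match.arg(p_method)
  stopifnot(sdt_a$B == sdt_b$B)
  B <- sdt_a$B
  one <- function(what) {
    d_obs <- sdt_b[[what]] - sdt_a[[what]]
    d_rep <- sdt_b$reps[[what]] - sdt_a$reps[[what]]
    p <- if (p_method == "sign_reversal") {
      if (d_obs >= 0) mean(d_rep <= 0) else mean(d_rep >= 0)
    } else {
      mean(d_rep >= d_obs)
    }
    data.frame(measure = what, diff = d_obs,
               ci_lo = stats::quantile(d_rep, 0.05, names = FALSE),
               ci_hi = stats::quantile(d_rep, 0.95, names = FALSE),
               p = max(p, 1 / B))
  }
  rbind(one("dprime"), one("c"))
}
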