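# Neural modulation statistics: z-scoring against baseline, the conjunction
# criterion (|z| > 3 AND distribution test P < 0.05) for MUA and single
# units, PSTHs, autocorrelograms, orientation-tuning fits, and session-long
# rate stability.

window_idx <- function(tensor, window) {
  tt <- tensor_time(tensor)
  which(tt >= window[1] & tt < window[2])
}

#' Z-score a trial tensor against a baseline window
#'
#' Averages over trials, then standardizes each channel by the mean and SD
#' of the baseline samples of its trial-averaged trace.
#'
#' @param tensor [epoch_align()] output.
#' @param baseline length-2 window in seconds, inside the tensor window.
#' @return channels x time matrix of z values.
#' @export
zscore_to_baseline <- function(tensor, baseline) {
  stopifnot(baseline[1] >= tensor$window[1], baseline[2] <= tensor$window[2])
  avg <- apply(tensor$data, c(2, 3), mean)      # channels x time
  if (!is.matrix(avg)) avg <- matrix(avg, nrow = dim(tensor$data)[2])
  bi <- window_idx(tensor, baseline)
  if (length(bi) < 2) stop("baseline window too short")
  mu <- rowMeans(avg[, bi, drop = FALSE])
  sd <- apply(avg[, bi, drop = FALSE], 1, stats::sd)
  zero <- which(sd == 0)
  if (length(zero))
    stop("zero baseline variance on channel(s): ",
         paste(zero, collapse = ", "))
  (avg - mu) / sd
}

#' Classify MUA modulation per channel
#'
#' A channel is modulated when the trial-averaged MUA exceeds 3 baseline
#' SDs in absolute value within the stimulus window AND the distribution of
#' trial-averaged MUA samples differs between baseline and stimulus window
#' (two-sided Kolmogorov-Smirnov, P < 0.05). Defaults: visual baseline
#' -0.25..0 s and stimulus 0..0.65 s; optogenetic baseline -25..0 ms and
#' stimulus 0..25 ms (set via `cfg`).
#'
#' @param tensor [epoch_align()] output (trials x channels x time).
#' @param baseline,stim windows, seconds; disjoint.
#' @param cfg [analysis_config()].
#' @param ks_units `"timepoints"` (default; KS over samples of the
#'   trial-averaged trace) or `"trials"` (KS over per-trial window means).
#' @return data.frame, one row per channel: `max_abs_z`, `p_value`,
#'   `modulated`, plus the windows used, with the z profiles in
#'   `attr(, "z")`.
#' @export
classify_mua_modulation <- function(tensor, baseline = NULL, stim = NULL,
                                    cfg = analysis_config(),
                                    ks_units = c("timepoints", "trials")) {
  ks_units <- match.arg(ks_units)
  if (is.null(baseline)) baseline <- cfg$visual_baseline
  if (is.null(stim)) stim <- cfg$visual_stim
  if (max(baseline[1], stim[1]) < min(baseline[2], stim[2]))
    stop("baseline and stimulus windows must be disjoint")
  bi <- window_idx(tensor, baseline)
  si <- window_idx(tensor, stim)
  if (length(bi) < 5 || length(si) < 5)
    stop("fewer than 5 samples in a test window")
  z <- zscore_to_baseline(tensor, baseline)
  avg <- apply(tensor$data, c(2, 3), mean)
  nch <- dim(tensor$data)[2]
  p <- numeric(nch)
  for (ch in seq_len(nch)) {
    if (ks_units == "timepoints") {
      a <- avg[ch, bi]; b <- avg[ch, si]
    } else {
      a <- apply(tensor$data[, ch, bi, drop = FALSE], 1, mean)
      b <- apply(tensor$data[, ch, si, drop = FALSE], 1, mean)
    }
    p[ch] <- suppressWarnings(stats::ks.test(a, b)$p.value)
  }
  max_abs_z <- apply(abs(z[, si, drop = FALSE]), 1, max)
  res <- data.frame(channel = seq_len(nch), max_abs_z = max_abs_z,
                    p_value = p,
                    modulated = max_abs_z > cfg$z_threshold & p < cfg$ks_alpha,
                    baseline_lo = baseline[1], baseline_hi = baseline[2],
                    stim_lo = stim[1], stim_hi = stim[2])
  attr(res, "z") <- z
  res
}

#' Classify single-unit optogenetic modulation
#'
#' Per-trial spike counts in the stimulus window are compared between the
#' stimulation and control conditions by a two-sided Wilcoxon rank-sum test,
#' combined with the requirement that the trial-averaged rate exceeds 3
#' baseline SDs. Stimulus window matches the laser duration (0-0.25 s or
#' 0-0.20 s depending on session).
#'
#' @param unit [spike_cluster()].
#' @param stim_events,control_events event times (s) for the two groups.
#' @param stim_window stimulus window, seconds from event.
#' @param baseline_window baseline window, seconds from event.
#' @param cfg [analysis_config()].
#' @return one-row data.frame: `max_abs_z`, `p_value`, `modulated`.
#' @export
classify_sua_modulation <- function(unit, stim_events, control_events,
                                    stim_window = c(0, 0.25),
                                    baseline_window = c(-0.25, 0),
                                    cfg = analysis_config()) {
  if (!length(stim_events) || !length(control_events))
    stop("empty event group")
  counts_in <- function(events, win) {
    vapply(events, function(e)
      sum(unit$spike_times >= e + win[1] & unit$spike_times < e + win[2]),
      numeric(1))
  }
  a <- counts_in(stim_events, stim_window)
  b <- counts_in(control_events, stim_window)
  if (length(unit$spike_times) == 0 || (all(a == a[1]) && all(b == b[1]) &&
                                        a[1] == b[1]))
    return(data.frame(unit_id = unit$unit_id, max_abs_z = 0, p_value = 1,
                      modulated = FALSE))
  p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  # trial-averaged rate profile (1 ms bins) for the z criterion
  psth <- compute_psth(unit$spike_times, stim_events,
                       c(baseline_window[1], stim_window[2]), sigma = 0.005)
  bl <- psth$rate[psth$time >= baseline_window[1] &
                  psth$time < baseline_window[2]]
  st <- psth$rate[psth$time >= stim_window[1] & psth$time < stim_window[2]]
  sdb <- stats::sd(bl)
  z <- if (is.na(sdb) || sdb == 0) 0 else max(abs(st - mean(bl))) / sdb
  data.frame(unit_id = unit$unit_id, max_abs_z = z, p_value = p,
             modulated = z > cfg$z_threshold & p < cfg$ranksum_alpha)
}

gauss_kernel <- function(sigma, dt) {
  half <- max(1L, ceiling(4 * sigma / dt))
  k <- stats::dnorm(seq(-half, half) * dt, sd = sigma)
  k / sum(k)
}

#' Peristimulus time histogram
#'
#' Per-trial spike counts in 1 ms bins, smoothed with a Gaussian kernel
#' (truncated at 4 sigma, unit integral) and averaged across trials.
#'
#' @param spike_times seconds.
#' @param events alignment times, seconds.
#' @param window length-2 window, seconds relative to event.
#' @param sigma Gaussian SD, seconds (10 ms for visual, 2 ms for
#'   optogenetic displays).
#' @return list: `time` (s, relative), `rate` (spikes/s), `sem`.
#' @export
compute_psth <- function(spike_times, events, window, sigma = 0.010) {
  stopifnot(sigma > 0, length(events) >= 1)
  dt <- 0.001
  edges <- seq(window[1], window[2], by = dt)
  nb <- length(edges) - 1
  k <- gauss_kernel(sigma, dt)
  rates <- matrix(0, length(events), nb)
  for (i in seq_along(events)) {
    rel <- spike_times - events[i]
    rel <- rel[rel >= window[1] & rel < window[2]]
    cnt <- if (length(rel)) {
      tabulate(pmin(nb, floor((rel - window[1]) / dt) + 1), nbins = nb)
    } else numeric(nb)
    sm <- stats::convolve(cnt, rev(k), type = "open")
    half <- (length(k) - 1) / 2
    rates[i, ] <- sm[(half + 1):(half + nb)] / dt
  }
  list(time = edges[-length(edges)] + dt / 2,
       rate = colMeans(rates),
       sem = apply(rates, 2, stats::sd) / sqrt(length(events)))
}

#' Normalized autocorrelogram
#'
#' Histogram of all pairwise spike-time lags at 0.33 ms resolution over
#' +/-50 ms, with the central (zero-lag) bin removed, scaled by its maximum.
#' Symmetric by construction.
#'
#' @param spike_times seconds, sorted.
#' @param bin bin width, seconds.
#' @param max_lag lag span, seconds.
#' @return list: `lag` (bin centers, s), `acg` (normalized counts).
#' @export
autocorrelogram <- function(spike_times, bin = 0.00033, max_lag = 0.050) {
  if (length(spike_times) < 2) stop("need at least 2 spikes")
  if (is.unsorted(spike_times)) stop("spike_times must be sorted")
  pos <- cpp_lag_counts(spike_times, bin, max_lag)
  # first positive bin [0, bin) holds the residual central peak; drop it
  pos[1] <- 0L
  counts <- c(rev(pos), pos)
  lag <- c(-rev(seq_along(pos) - 0.5), seq_along(pos) - 0.5) * bin
  mx <- max(counts)
  list(lag = lag, acg = if (mx > 0) counts / mx else counts)
}

#' Fit an orientation tuning curve
#'
#' Least-squares fit of the 180 degree-periodic von Mises descriptor
#' `R(theta) = b + a * exp(kappa * (cos(2*(theta - theta_pref)) - 1))` to
#' mean rates per orientation. Descriptive only; no significance claim.
#'
#' @param orientation degrees.
#' @param rate mean rate per orientation.
#' @return list of class `tuning_fit`: `b`, `a`, `kappa`,
#'   `theta_pref` (degrees in `[0, 180)`), `residual` (RSS), `fitted`.
#' @export
fit_orientation_tuning <- function(orientation, rate) {
  stopifnot(length(orientation) == length(rate))
  if (length(unique(orientation)) < 4)
    stop("need at least 4 distinct orientations")
  th <- orientation * pi / 180
  if (max(rate) - min(rate) < 1e-12) {
    out <- list(b = mean(rate), a = 0, kappa = 0,
                theta_pref = 0, residual = 0, fitted = rate)
    class(out) <- "tuning_fit"
    return(out)
  }
  model <- function(par) {
    par[1] + par[2] * exp(par[3] * (cos(2 * (th - par[4])) - 1))
  }
  obj <- function(par) {
    if (par[3] < 0) return(1e12)
    sum((rate - model(par))^2)
  }
  best <- NULL
  for (th0 in seq(0, pi, length.out = 9)[-9]) {
    fit <- stats::optim(c(min(rate), max(rate) - min(rate), 1, th0), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  par <- best$par
  tp <- (par[4] * 180 / pi) %% 180
  out <- list(b = par[1], a = par[2], kappa = max(par[3], 0),
              theta_pref = tp, residual = best$value, fitted = model(par))
  class(out) <- "tuning_fit"
  out
}

#' Session-long firing-rate stability
#'
#' Gaussian-smoothed (sigma = 2 s) firing rate across the whole session,
#' with the first and last 5 s excluded from the output span.
#'
#' @param spike_times seconds.
#' @param span length-2 session span, seconds (>= 20 s long).
#' @param sigma smoothing SD, seconds.
#' @param edge_trim seconds removed at each end.
#' @return list: `time` (s), `rate` (spikes/s) over `[span1+5, span2-5]`.
#' @export
firing_rate_stability <- function(spike_times, span, sigma = 2,
                                  edge_trim = 5) {
  if (diff(span) < 20) stop("session must be at least 20 s long")
  dt <- 0.1
  edges <- seq(span[1], span[2], by = dt)
  nb <- length(edges) - 1
  cnt <- if (length(spike_times)) {
    st <- spike_times[spike_times >= span[1] & spike_times < span[2]]
    tabulate(pmin(nb, floor((st - span[1]) / dt) + 1), nbins = nb)
  } else numeric(nb)
  k <- gauss_kernel(sigma, dt)
  half <- (length(k) - 1) / 2
  sm <- stats::convolve(cnt, rev(k), type = "open")[(half + 1):(half + nb)] / dt
  tt <- edges[-length(edges)] + dt / 2
  keep <- tt >= span[1] + edge_trim & tt <= span[2] - edge_trim
  list(time = tt[keep], rate = sm[keep])
}
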