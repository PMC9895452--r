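# Shared data model. Times are seconds, double precision, session-relative
# (t = 0 at recording start); all windows half-open [start, end).

CONDITION_LEVELS <- c("high", "high_opto", "low", "low_opto",
                      "opto_only", "sham", "catch")
OUTCOME_LEVELS <- c("hit", "miss", "false_alarm", "correct_rejection",
                    "early", "excluded")

#' Multichannel voltage trace with probe geometry
#'
#' @param samples channels-by-time numeric matrix, microvolts.
#' @param rate sampling rate, Hz.
#' @param channel_map data.frame with columns `channel`, `shank`, `site`
#'   (within-shank index, 0-based), `depth_um`.
#' @param t0 session time of the first sample, seconds.
#' @return object of class `recording_block`.
#' @export
recording_block <- function(samples, rate, channel_map, t0 = 0) {
  samples <- as.matrix(samples)
  stopifnot(rate > 0, is.data.frame(channel_map))
  need <- c("channel", "shank", "site", "depth_um")
  miss <- setdiff(need, names(channel_map))
  if (length(miss))
    stop("channel_map missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(channel_map) != nrow(samples))
    stop("channel_map rows (", nrow(channel_map),
         ") != channel count (", nrow(samples), ")")
  for (sh in unique(channel_map$shank)) {
    sites <- channel_map$site[channel_map$shank == sh]
    if (anyDuplicated(sites))
      stop("duplicate within-shank site index on shank ", sh)
    d <- sort(channel_map$depth_um[channel_map$shank == sh])
    if (length(d) > 1) {
      sp <- diff(d)
      if (any(sp <= 0) || max(sp) - min(sp) > 1e-6)
        stop("depth spacing on shank ", sh, " is not a positive constant")
    }
  }
  structure(list(samples = samples, rate = rate,
                 channel_map = channel_map, t0 = t0),
            class = "recording_block")
}

#' @export
print.recording_block <- function(x, ...) {
  cat(sprintf("<recording_block> %d ch x %d samples @ %g Hz, %d shank(s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              length(unique(x$channel_map$shank))))
  invisible(x)
}

#' Eye-position trace
#'
#' @param t time, seconds (uniformly sampled).
#' @param x,y gaze position, degrees of visual angle (+x right, +y up).
#' @param rate sampling rate, Hz.
#' @param blink logical blink mask per sample.
#' @return object of class `eye_trace`.
#' @export
eye_trace <- function(t, x, y, rate, blink = rep(FALSE, length(t))) {
  stopifnot(length(t) == length(x), length(x) == length(y),
            length(blink) == length(t), rate > 0)
  if (length(t) > 1) {
    dt <- diff(t)
    if (max(abs(dt - 1 / rate)) > 1e-6 / rate)
      stop("eye trace is not uniformly sampled at the stated rate")
  }
  structure(list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                 rate = rate, blink = as.logical(blink)),
            class = "eye_trace")
}

#' Spike-sorted cluster
#'
#' @param unit_id identifier.
#' @param spike_times seconds, nondecreasing.
#' @param snippets spikes x channels x samples array of waveform snippets
#'   (microvolts), or `NULL`.
#' @param mean_waveform channels x samples matrix; computed from `snippets`
#'   by [trimmed_mean_waveform()] when omitted.
#' @param peak_channel index of the channel with the largest peak-to-trough
#'   amplitude of `mean_waveform`; derived when omitted.
#' @return object of class `spike_cluster`.
#' @export
spike_cluster <- function(unit_id, spike_times, snippets = NULL,
                          mean_waveform = NULL, peak_channel = NULL) {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times))
    stop("spike_times must be nondecreasing for unit ", unit_id)
  if (is.null(mean_waveform) && !is.null(snippets))
    mean_waveform <- trimmed_mean_waveform(snippets)
  if (is.null(peak_channel) && !is.null(mean_waveform))
    peak_channel <- which.max(apply(mean_waveform, 1,
                                    function(w) diff(range(w))))
  structure(list(unit_id = unit_id, spike_times = spike_times,
                 snippets = snippets, mean_waveform = mean_waveform,
                 peak_channel = peak_channel),
            class = "spike_cluster")
}

#' Construct / validate a trial table
#'
#' Normalizes condition labels (`+` to `_`), enforces the closed condition
#' set, strictly increasing event times where present, and leaves outcomes
#' blank for unscored trials.
#'
#' @param df data.frame with columns `trial_id`, `condition`, `fixation_on`,
#'   `background_on`, `target_on`, `laser_on`, `response_time`, `outcome`
#'   (missing optional columns are added as `NA`).
#' @return validated data.frame of class `trial_table`.
#' @export
trial_table <- function(df) {
  need <- c("trial_id", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trial table missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("fixation_on", "background_on", "target_on", "laser_on",
                "response_time"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_ else
      df[[col]] <- as.numeric(df[[col]])
  if (is.null(df$outcome)) df$outcome <- NA_character_
  df$outcome[!is.na(df$outcome) & df$outcome == ""] <- NA_character_
  df$condition <- gsub("+", "_", as.character(df$condition), fixed = TRUE)
  bad <- setdiff(unique(df$condition), CONDITION_LEVELS)
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  badout <- setdiff(unique(df$outcome[!is.na(df$outcome)]), OUTCOME_LEVELS)
  if (length(badout))
    stop("unknown outcome label(s): ", paste(badout, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    ev <- c(df$fixation_on[i], df$background_on[i], df$target_on[i],
            df$laser_on[i])
    ev <- ev[!is.na(ev)]
    if (length(ev) > 1 && any(diff(ev) <= 0))
      stop("nonmonotonic event times in trial ", df$trial_id[i])
    if (df$condition[i] == "catch" && !is.na(df$target_on[i]))
      stop("catch trial ", df$trial_id[i],
           " has target_on; catch trials present no target")
    if (!is.na(df$response_time[i]) && length(ev) &&
        df$response_time[i] < ev[1])
      stop("response_time precedes first event in trial ", df$trial_id[i])
  }
  class(df) <- c("trial_table", "data.frame")
  df
}

#' @rdname trial_table
#' @param table a parsed trial table (data.frame).
#' @export
validate_trial_table <- function(table) trial_table(as.data.frame(table))

#' Pipeline configuration with the study's default constants
#'
#' Every threshold and window of the analysis chain, overridable by name.
#' Defaults: |z| > 3 and two-sided KS / rank-sum alpha 0.05 for modulation;
#' ISI violation limit 2.5% below 1.5 ms; template correlation 0.95; spatial
#' spread < 5 channels; RF epoch -100..180 ms with paired t alpha 0.01;
#' saccade velocity threshold 50 deg/s with 3 ms smoothing; hit window
#' 50-500 ms; catch fixation 800 ms; bootstrap B = 10000; false-alarm
#' resampling 1000 replicates.
#'
#' @param ... named overrides.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    z_threshold = 3,
    ks_alpha = 0.05,
    ranksum_alpha = 0.05,
    visual_baseline = c(-0.25, 0),
    visual_stim = c(0, 0.65),
    opto_baseline = c(-0.025, 0),
    opto_stim = c(0, 0.025),
    isi_refractory_s = 0.0015,
    isi_violation_limit = 0.025,
    template_r_min = 0.95,
    spread_max_channels = 5,
    rf_epoch = c(-0.1, 0.18),
    rf_alpha = 0.01,
    rf_min_wedges = 3,
    rf_min_annuli = 3,
    rf_noise_factor = 10,
    rf_outline_level = 0.2,
    saccade_velocity_threshold = 50,
    saccade_smooth_sigma = 0.003,
    saccade_endpoint_window = 0.025,
    saccade_merge_gap = 0.010,
    hit_window = c(0.05, 0.5),
    catch_fixation_s = 0.8,
    catch_fraction = 0.4,
    bootstrap_B = 10000,
    fa_resample_reps = 1000,
    taper_s = 0.005,
    seed = 1L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  for (nm in setdiff(names(cfg), "seed")) {
    v <- cfg[[nm]]
    if (is.numeric(v) && nm %in% c("z_threshold", "isi_violation_limit",
                                   "template_r_min", "ks_alpha",
                                   "ranksum_alpha", "rf_alpha"))
      if (any(v <= 0)) stop("config field ", nm, " must be strictly positive")
    if (grepl("alpha|limit|fraction", nm) && is.numeric(v) &&
        any(v <= 0 | v >= 1))
      stop("config field ", nm, " must lie in (0, 1)")
  }
  class(cfg) <- "analysis_config"
  cfg
}

#' Deterministic named random streams
#'
#' Derives an independent integer seed from a base seed and a stream name so
#' that different pipeline stages draw from decoupled, reproducible streams.
#'
#' @param seed base seed, nonnegative integer.
#' @param stream stream name.
#' @return integer seed below 2^31, suitable for [set.seed()].
#' @export
seeded_rng <- function(seed, stream = "default") {
  stopifnot(seed >= 0)
  m <- 2147483647  # Mersenne prime keeps every product below 2^53
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% m
  s <- as.numeric(seed) %% m
  s <- (s * 69069 + 12345) %% m
  as.integer((s * 69069 + h + 1) %% m)
}

#' Evaluate an expression under a named random stream
#'
#' Restores the caller's RNG state afterwards.
#'
#' @inheritParams seeded_rng
#' @param expr expression to evaluate.
#' @export
with_rng_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seeded_rng(seed, stream))
  expr
}
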