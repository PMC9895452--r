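# Curation of externally sorted clusters (the sorter is an upstream
# producer). Three acceptance rules, all required: refractory-period ISI
# violations <= 2.5% below 1.5 ms, peak-channel waveform correlated >= 0.95
# with at least one of 20 reference templates, and spatial spread
# concentrated within < 5 channels at half peak amplitude.

#' Trimmed-mean waveform
#'
#' Per channel and time sample, the mean after excluding the extreme 5% of
#' values (2.5% per tail). With fewer than 20 snippets the plain mean is
#' returned with a warning.
#'
#' @param snippets spikes x channels x samples array.
#' @param trim total fraction excluded.
#' @return channels x samples matrix.
#' @export
trimmed_mean_waveform <- function(snippets, trim = 0.05) {
  stopifnot(length(dim(snippets)) == 3)
  if (dim(snippets)[1] < 20) {
    warning("fewer than 20 snippets; returning plain mean")
    return(apply(snippets, c(2, 3), mean))
  }
  apply(snippets, c(2, 3), mean, trim = trim / 2)
}

#' Refractory-period violation check
#'
#' Fraction of inter-spike intervals below 1.5 ms; a cluster passes unless
#' strictly more than 2.5% of ISIs violate.
#'
#' @param spike_times seconds, sorted ascending.
#' @param refractory_s violation threshold, seconds.
#' @param limit maximal tolerated violation fraction.
#' @param units `"isi"` (fraction of ISIs, default) or `"spikes"`
#'   (violating spikes over all spikes).
#' @return list: `fraction`, `pass`.
#' @export
isi_violation_check <- function(spike_times, refractory_s = 0.0015,
                                limit = 0.025, units = c("isi", "spikes")) {
  units <- match.arg(units)
  if (length(spike_times) < 2) stop("need at least 2 spikes")
  if (is.unsorted(spike_times)) stop("spike_times must be sorted")
  isi <- diff(spike_times)
  nviol <- sum(isi < refractory_s)
  frac <- if (units == "isi") nviol / length(isi)
          else nviol / length(spike_times)
  list(fraction = frac, pass = frac <= limit)
}

#' Template-similarity check
#'
#' Maximum Pearson correlation between the peak-channel mean waveform and a
#' library of reference templates (linearly resampled to the waveform's
#' sample count); pass requires r >= 0.95.
#'
#' @param waveform numeric vector (peak-channel mean waveform).
#' @param templates matrix, one template per row, or list of vectors.
#' @param r_min acceptance threshold.
#' @return list: `max_r`, `pass`, `best_template`.
#' @export
template_similarity_check <- function(waveform, templates, r_min = 0.95) {
  if (is.list(templates)) templates <- do.call(rbind, templates)
  if (stats::sd(waveform) == 0)
    return(list(max_r = NA_real_, pass = FALSE, best_template = NA_integer_))
  n <- length(waveform)
  rs <- apply(templates, 1, function(tp) {
    if (length(tp) != n)
      tp <- stats::approx(seq_along(tp), tp, n = n)$y
    if (stats::sd(tp) == 0) return(-Inf)
    stats::cor(waveform, tp)
  })
  list(max_r = max(rs), pass = max(rs) >= r_min,
       best_template = which.max(rs))
}

#' Spatial-spread check
#'
#' Counts channels whose waveform amplitude (peak-to-trough of the mean
#' waveform) exceeds 50% of the peak channel's amplitude; pass requires the
#' cluster to be concentrated within < 5 channels.
#'
#' @param mean_waveform channels x samples matrix.
#' @param max_channels strict upper bound on the count.
#' @return list: `n_channels`, `pass`.
#' @export
spatial_spread_check <- function(mean_waveform, max_channels = 5) {
  amp <- apply(mean_waveform, 1, function(w) diff(range(w)))
  n <- sum(amp > 0.5 * max(amp))
  list(n_channels = n, pass = n < max_channels)
}

#' Curate a set of clusters
#'
#' Applies all three acceptance rules; a cluster is accepted iff all pass.
#'
#' @param clusters list of [spike_cluster()].
#' @param templates reference template library (see
#'   [waveform_template_library()]).
#' @param cfg [analysis_config()].
#' @return data.frame of class `qc_report`: one row per cluster with
#'   `isi_violation_fraction`, `max_template_r`, `spread_channels`,
#'   `accepted`, `reasons` (comma-joined failed rules).
#' @export
curate_clusters <- function(clusters, templates = waveform_template_library(),
                            cfg = analysis_config()) {
  rows <- lapply(clusters, function(cl) {
    mw <- cl$mean_waveform
    if (is.null(mw)) mw <- trimmed_mean_waveform(cl$snippets)
    pk <- cl$peak_channel %||%
      which.max(apply(mw, 1, function(w) diff(range(w))))
    isi <- isi_violation_check(cl$spike_times, cfg$isi_refractory_s,
                               cfg$isi_violation_limit)
    tmp <- template_similarity_check(mw[pk, ], templates, cfg$template_r_min)
    spr <- spatial_spread_check(mw, cfg$spread_max_channels)
    reasons <- c(if (!isi$pass) "isi", if (!tmp$pass) "template",
                 if (!spr$pass) "spread")
    data.frame(unit_id = as.character(cl$unit_id),
               isi_violation_fraction = isi$fraction,
               max_template_r = tmp$max_r %||% NA_real_,
               spread_channels = spr$n_channels,
               accepted = isi$pass && tmp$pass && spr$pass,
               reasons = paste(reasons, collapse = ","))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Reference library of plausible spike waveform templates
#'
#' Twenty synthetic biphasic shapes spanning trough-to-peak widths of
#' 0.3-1.2 ms at 25 kHz, standing in for the study's manually selected
#' templates (which are not available). Shipped as a text fixture and
#' regenerable from code.
#'
#' @param n_samples samples per template.
#' @param rate sampling rate, Hz.
#' @return 20 x `n_samples` matrix, one template per row.
#' @export
waveform_template_library <- function(n_samples = 61, rate = 25000) {
  widths_ms <- seq(0.3, 1.2, length.out = 20)
  t <- (seq_len(n_samples) - (n_samples + 1) / 2) / rate  # s, trough at 0
  out <- t(vapply(widths_ms, function(w) {
    biphasic_template(t, w / 1000)
  }, numeric(n_samples)))
  rownames(out) <- sprintf("tmpl_w%.2fms", widths_ms)
  out
}

# Canonical biphasic extracellular shape: sharp negative trough followed by
# a slower positive afterwave; `width_s` is the trough-to-peak time.
biphasic_template <- function(t, width_s) {
  tau1 <- width_s / 3
  w <- -exp(-(t / tau1)^2) + 0.45 * exp(-((t - width_s) / (1.6 * tau1))^2)
  w / max(abs(w))
}
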