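# Raw-trace conditioning: offline resampling to 25 kHz, per-shank common
# median re-referencing, spike-band filtering, and the 1 kHz MUA envelope
# (full-wave rectification -> Chebyshev II low-pass -> decimation).
# Filters run causally as SOS cascades; group delay is documented, not
# corrected, so downstream tests use phase-insensitive quantities.

TDT_RATE <- 24414.0625  # 25 MHz / 1024

#' Resample a raw trace to exactly 25 kHz
#'
#' Rational polyphase resampling by 128/125 (24414.0625 Hz -> 25000 Hz).
#' Traces already at 25 kHz pass through with a warning; other rates are an
#' error.
#'
#' @param block [recording_block()] at 24414.0625 Hz.
#' @return [recording_block()] at 25000 Hz.
#' @export
resample_to_25k <- function(block) {
  if (abs(block$rate - 25000) < 1e-6) {
    warning("recording already at 25 kHz; passing through")
    return(block)
  }
  if (abs(block$rate - TDT_RATE) > 1e-4)
    stop("resample_to_25k expects ", TDT_RATE, " Hz input, got ", block$rate)
  out <- resample_rational(block$samples, 128L, 125L)
  recording_block(out, 25000, block$channel_map, t0 = block$t0)
}

#' Per-shank common median re-reference
#'
#' Subtracts, sample by sample, the median across all channels of a shank
#' from each channel of that shank. Shanks are processed independently.
#'
#' @param block [recording_block()].
#' @return re-referenced [recording_block()].
#' @export
median_rereference <- function(block) {
  out <- block$samples
  for (sh in unique(block$channel_map$shank)) {
    rows <- which(block$channel_map$shank == sh)
    if (!length(rows)) stop("shank ", sh, " has no channels")
    med <- if (length(rows) == 1) out[rows, , drop = TRUE]
           else apply(out[rows, , drop = FALSE], 2, stats::median)
    out[rows, ] <- sweep(out[rows, , drop = FALSE], 2, med)
  }
  recording_block(out, block$rate, block$channel_map, t0 = block$t0)
}

#' Spike-band filter designs
#'
#' `butter4_300_6000`: 4th-order Butterworth band-pass 0.3-6 kHz.
#' `cheby2_40_300_8000`: 40th-order Chebyshev type II band filter 0.3-8 kHz
#' with 200 dB stopband attenuation, realized as a 20th-order high-pass
#' (edge 300 Hz) cascaded with a 20th-order low-pass (edge 8 kHz); used when
#' optogenetic stimulation requires strong rejection of low-frequency
#' photo-artifact.
#'
#' @param design design name.
#' @param rate sampling rate, Hz (>= 25 kHz).
#' @return SOS matrix.
#' @export
spikeband_design <- function(design = c("butter4_300_6000",
                                        "cheby2_40_300_8000"), rate) {
  design <- match.arg(design)
  stopifnot(rate >= 25000)
  switch(design,
    butter4_300_6000 =
      design_sos("butter_bandpass", 4, c(300, 6000), rate),
    cheby2_40_300_8000 =
      rbind(design_sos("cheby2_highpass", 20, 300, rate, rs = 200),
            design_sos("cheby2_lowpass", 20, 8000, rate, rs = 200))
  )
}

#' Band-pass filter a trace into the spike band
#'
#' @param block [recording_block()] (or plain matrix/vector with `rate`).
#' @param design see [spikeband_design()].
#' @param rate required when `block` is not a `recording_block`.
#' @return filtered object of the same kind as the input.
#' @export
bandpass_spikeband <- function(block, design = "butter4_300_6000",
                               rate = NULL) {
  if (inherits(block, "recording_block")) {
    sos <- spikeband_design(design, block$rate)
    recording_block(sos_filter(sos, block$samples), block$rate,
                    block$channel_map, t0 = block$t0)
  } else {
    stopifnot(!is.null(rate))
    sos_filter(spikeband_design(design, rate), block)
  }
}

#' 1 kHz multi-unit activity envelope
#'
#' Full-wave rectification, 6th-order Chebyshev type II low-pass (stopband
#' edge 500 Hz, 50 dB attenuation), then decimation to 1 kHz keeping every
#' 25th sample starting at sample 0. Negative values from filter ringing
#' are clipped to 0 (envelope semantics).
#'
#' @param x spike-band trace: `recording_block`, matrix (channels x time) or
#'   vector at 25 kHz.
#' @param rate sampling rate when `x` is not a `recording_block`.
#' @return object of class `mua_series`: list with `values` (channels x
#'   time matrix, nonnegative), `rate` (1000), `t0`, `provenance`.
#' @export
compute_mua <- function(x, rate = NULL) {
  if (inherits(x, "recording_block")) {
    rate <- x$rate
    t0 <- x$t0
    v <- x$samples
  } else {
    stopifnot(!is.null(rate))
    t0 <- 0
    v <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  }
  dec <- rate / 1000
  if (abs(dec - round(dec)) > 1e-9)
    stop("rate ", rate, " Hz is not an integer multiple of 1 kHz")
  dec <- as.integer(round(dec))
  sos <- design_sos("cheby2_lowpass", 6, 500, rate, rs = 50)
  env <- sos_filter(sos, abs(v))
  keep <- seq(1, ncol(env), by = dec)
  out <- pmax(env[, keep, drop = FALSE], 0)
  structure(list(values = out, rate = 1000, t0 = t0,
                 provenance = "rectify+cheby2_6_500_50dB+decim"),
            class = "mua_series")
}

#' @export
print.mua_series <- function(x, ...) {
  cat(sprintf("<mua_series> %d ch x %d samples @ 1 kHz\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Epoch a series around events
#'
#' Cuts exact-sample-aligned epochs from a 1 kHz MUA series (or any
#' channels x time matrix) around event times, window half-open
#' `[window[1], window[2])` relative to each event.
#'
#' @param series `mua_series` or matrix with `rate`/`t0` supplied.
#' @param events event times, seconds.
#' @param window length-2 numeric, seconds relative to the event.
#' @param rate,t0 used when `series` is a plain matrix.
#' @return object of class `trial_tensor`: `data` (trials x channels x
#'   time), `window`, `rate`, `events`.
#' @export
epoch_align <- function(series, events, window, rate = NULL, t0 = 0) {
  if (inherits(series, "mua_series")) {
    v <- series$values; rate <- series$rate; t0 <- series$t0
  } else {
    v <- if (is.matrix(series)) series else matrix(series, nrow = 1)
    stopifnot(!is.null(rate))
  }
  nsamp <- round((window[2] - window[1]) * rate)
  start_idx <- round((events + window[1] - t0) * rate) + 1
  bad <- start_idx < 1 | (start_idx + nsamp - 1) > ncol(v)
  if (any(bad))
    stop("event(s) out of series span: ",
         paste(signif(events[bad], 6), collapse = ", "))
  dat <- array(0, dim = c(length(events), nrow(v), nsamp))
  for (i in seq_along(events))
    dat[i, , ] <- v[, start_idx[i]:(start_idx[i] + nsamp - 1), drop = FALSE]
  structure(list(data = dat, window = window, rate = rate, events = events),
            class = "trial_tensor")
}

#' Time axis of a trial tensor
#' @param tensor `trial_tensor`.
#' @return sample times relative to the alignment event, seconds.
#' @export
tensor_time <- function(tensor)
  tensor$window[1] + (seq_len(dim(tensor$data)[3]) - 1) / tensor$rate
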