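# Receptive-field mapping from sparse wedge/annulus stimuli: epoch
# selection with a fixation gate, variance-based noise rejection, the
# "at least 3 wedges AND 3 annuli significant" modulation criterion, and a
# normalized polar map with a 0.2-level outline. The map reconstruction is
# a product of the normalized marginal response profiles, a documented
# stand-in for the original back-projection.

#' Cut RF-mapping epochs with a fixation gate
#'
#' Epochs of 280 ms (-100..+180 ms around stimulus onset) at 1 kHz; an
#' epoch is kept only if every eye sample in it stays inside the fixation
#' window.
#'
#' @param mua `mua_series` (single channel used; pass `channel`).
#' @param stim data.frame with `onset` (s) and `stim_id`.
#' @param eye [eye_trace()] or `NULL` to skip the gate.
#' @param fix_radius fixation window radius, degrees.
#' @param fix_center fixation point, degrees.
#' @param channel channel of `mua` to epoch.
#' @param cfg [analysis_config()].
#' @return list of class `rf_epochs`: `data` (epochs x time), `stim_id`,
#'   `onset`, `time` (s relative to onset).
#' @export
epoch_rf <- function(mua, stim, eye = NULL, fix_radius = 1.5,
                     fix_center = c(0, 0), channel = 1,
                     cfg = analysis_config()) {
  win <- cfg$rf_epoch
  keep <- rep(TRUE, nrow(stim))
  if (!is.null(eye)) {
    r <- sqrt((eye$x - fix_center[1])^2 + (eye$y - fix_center[2])^2)
    out_of_win <- r > fix_radius | eye$blink
    for (i in seq_len(nrow(stim))) {
      idx <- which(eye$t >= stim$onset[i] + win[1] &
                   eye$t < stim$onset[i] + win[2])
      if (any(out_of_win[idx])) keep[i] <- FALSE
    }
  }
  if (!any(keep)) stop("no eligible epochs after the fixation gate")
  st <- stim[keep, , drop = FALSE]
  tens <- epoch_align(mua, st$onset, win)
  dat <- tens$data[, channel, , drop = TRUE]
  if (is.null(dim(dat))) dat <- matrix(dat, nrow = nrow(st))
  structure(list(data = dat, stim_id = st$stim_id, onset = st$onset,
                 time = tensor_time(tens)),
            class = "rf_epochs")
}

#' Reject high-variance (noise) epochs
#'
#' Removes epochs whose across-time SD exceeds 10 times the median SD over
#' all epochs. Idempotent in practice on clean data.
#'
#' @param epochs `rf_epochs`.
#' @param factor rejection multiple of the median SD.
#' @return filtered `rf_epochs` with attribute `rejected` (indices).
#' @export
reject_noise_epochs <- function(epochs, factor = 10) {
  if (nrow(epochs$data) < 10)
    warning("fewer than 10 epochs; noise threshold is unstable")
  sds <- apply(epochs$data, 1, stats::sd)
  bad <- which(sds > factor * stats::median(sds))
  if (length(bad)) {
    epochs$data <- epochs$data[-bad, , drop = FALSE]
    epochs$stim_id <- epochs$stim_id[-bad]
    epochs$onset <- epochs$onset[-bad]
  }
  attr(epochs, "rejected") <- bad
  epochs
}

#' RF modulation criterion
#'
#' Per stimulus, a one-tailed paired t-test of the response-window mean
#' (0..180 ms) against the baseline mean (-100..0 ms) across epochs. A site
#' is modulated iff at least 3 wedge stimuli AND at least 3 annulus stimuli
#' are significant at P < 0.01.
#'
#' @param epochs `rf_epochs`.
#' @param geometry data.frame with `stim_id`, `kind` ("wedge"/"annulus"),
#'   `lo`, `hi` (polar angle degrees for wedges, eccentricity degrees for
#'   annuli).
#' @param cfg [analysis_config()].
#' @return list: `modulated`, `tests` (per-stimulus data.frame with mean
#'   response, SEM, p).
#' @export
classify_rf_modulation <- function(epochs, geometry, cfg = analysis_config()) {
  base_i <- epochs$time < 0
  resp_i <- epochs$time >= 0
  ids <- unique(epochs$stim_id)
  rows <- lapply(ids, function(id) {
    sel <- epochs$stim_id == id
    n <- sum(sel)
    if (n < 2) {
      warning("stimulus ", id, " has fewer than 2 epochs; skipped")
      return(NULL)
    }
    resp <- rowMeans(epochs$data[sel, resp_i, drop = FALSE])
    base <- rowMeans(epochs$data[sel, base_i, drop = FALSE])
    p <- if (stats::sd(resp - base) == 0) 1 else
      stats::t.test(resp, base, paired = TRUE,
                    alternative = "greater")$p.value
    data.frame(stim_id = id, n = n, mean_response = mean(resp - base),
               sem = stats::sd(resp - base) / sqrt(n), p_value = p)
    })
  tests <- do.call(rbind, rows)
  tests <- merge(tests, geometry, by = "stim_id", sort = FALSE)
  sig <- tests$p_value < cfg$rf_alpha
  n_wedge <- sum(sig & tests$kind == "wedge")
  n_annulus <- sum(sig & tests$kind == "annulus")
  list(modulated = n_wedge >= cfg$rf_min_wedges &&
                   n_annulus >= cfg$rf_min_annuli,
       n_sig_wedges = n_wedge, n_sig_annuli = n_annulus, tests = tests)
}

#' Build a normalized RF map with outline and centroid
#'
#' Combines the wedge (polar angle) and annulus (eccentricity) marginal
#' response profiles by their product on a polar grid, min-max normalizes
#' to `[0, 1]`, truncates at 0.2 for the outline, and reports the
#' response-weighted centroid over the supra-threshold region (circular
#' mean over polar angle).
#'
#' @param tests per-stimulus table from [classify_rf_modulation()] (needs
#'   `stim_id`, `mean_response`, `kind`, `lo`, `hi`).
#' @param n_angle,n_ecc grid resolution.
#' @param level outline truncation level.
#' @return list of class `rf_map`: `map` (ecc x angle in `[0,1]`),
#'   `ecc`, `angle` (bin centers, degrees), `outline` (logical mask),
#'   `centroid` (`ecc`, `angle` degrees or `NA` when empty).
#' @export
build_rf_map <- function(tests, n_angle = 24, n_ecc = 12, level = 0.2) {
  wedges <- tests[tests$kind == "wedge", , drop = FALSE]
  annuli <- tests[tests$kind == "annulus", , drop = FALSE]
  if (!nrow(wedges) || !nrow(annuli))
    stop("need both wedge and annulus responses")
  ang_span <- c(min(wedges$lo), max(wedges$hi))
  ecc_span <- c(min(annuli$lo), max(annuli$hi))
  angle <- seq(ang_span[1], ang_span[2], length.out = n_angle + 1)
  angle <- (angle[-1] + angle[-length(angle)]) / 2
  ecc <- seq(ecc_span[1], ecc_span[2], length.out = n_ecc + 1)
  ecc <- (ecc[-1] + ecc[-length(ecc)]) / 2
  profile_at <- function(tab, xs) {
    vapply(xs, function(x) {
      hit <- tab$lo <= x & x < tab$hi
      if (!any(hit)) 0 else mean(tab$mean_response[hit])
    }, numeric(1))
  }
  wa <- pmax(profile_at(wedges, angle), 0)
  ae <- pmax(profile_at(annuli, ecc), 0)
  norm01 <- function(v) {
    rng <- range(v)
    if (diff(rng) < 1e-300) rep(0, length(v)) else (v - rng[1]) / diff(rng)
  }
  m <- outer(norm01(ae), norm01(wa))
  if (max(m) > 0) m <- m / max(m)
  mask <- m > level
  centroid <- if (!any(mask)) c(ecc = NA_real_, angle = NA_real_) else {
    w <- m[mask]
    eg <- matrix(ecc, n_ecc, n_angle)[mask]
    ag <- matrix(angle, n_ecc, n_angle, byrow = TRUE)[mask]
    cs <- sum(w * cos(ag * pi / 180)) / sum(w)
    sn <- sum(w * sin(ag * pi / 180)) / sum(w)
    c(ecc = sum(w * eg) / sum(w), angle = atan2(sn, cs) * 180 / pi)
  }
  structure(list(map = m, ecc = ecc, angle = angle, outline = mask,
                 centroid = centroid, level = level),
            class = "rf_map")
}
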