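# Shared in-code fixtures. Everything is generated programmatically; no
# binary files ship with the package.

probe_map <- function(nch = 4, shank = 1L) {
  data.frame(channel = seq_len(nch), shank = shank,
             site = seq_len(nch) - 1L,
             depth_um = (seq_len(nch) - 1) * 25)
}

# samples exactly representable on the int16 x scale grid used by the
# bundle writer (scale = max|x|/32767)
quantized_samples <- function(nch, nt, seed = 1) {
  set.seed(seed)
  counts <- matrix(sample(-32767:32767, nch * nt, replace = TRUE), nch, nt)
  counts[1] <- 32767          # pin full scale so scale_uV is reproducible
  counts * (50 / 32767)       # 50 uV full scale
}

small_trials <- function() {
  trial_table(data.frame(
    trial_id = 1:7,
    condition = c("high", "high_opto", "low", "low_opto", "opto_only",
                  "sham", "catch"),
    fixation_on = (0:6) * 2,
    background_on = (0:6) * 2 + 0.12,
    target_on = c(0.32, 2.32, 4.32, 6.32, NA, NA, NA),
    laser_on = c(NA, 2.320001, NA, 6.320001, 8.32, 10.32, NA),
    response_time = c(0.52, 2.52, NA, 6.52, NA, NA, NA),
    outcome = NA_character_))
}

# synthetic cluster built from the template library: `kind` controls which
# QC rule it violates
make_cluster <- function(id, kind = c("good", "isi", "noise", "diffuse"),
                         n_spikes = 200, seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  tmpl <- waveform_template_library()[sample(20, 1), ] * 100
  nch <- 8
  peak <- sample(2:7, 1)
  decay <- exp(-abs(seq_len(nch) - peak) * 25 / 40)
  if (kind == "diffuse") decay <- rep(1, nch)
  n_snip <- 60
  snip <- array(0, c(n_snip, nch, length(tmpl)))
  for (s in seq_len(n_snip))
    for (ch in seq_len(nch))
      snip[s, ch, ] <- tmpl * decay[ch] + rnorm(length(tmpl), sd = 4)
  if (kind == "noise")
    for (s in seq_len(n_snip))
      snip[s, , ] <- array(rnorm(nch * length(tmpl), sd = 40),
                           c(nch, length(tmpl)))
  st <- cumsum(runif(n_spikes, 0.004, 0.04))
  if (kind == "isi") {
    n_bad <- ceiling(0.04 * n_spikes)
    st <- sort(c(st, st[sample(n_spikes, n_bad)] + 0.001))
  }
  spike_cluster(id, st, snippets = snip)
}

# independent high-precision inverse-normal oracle (bisection on pnorm)
qnorm_oracle <- function(p) {
  vapply(p, function(pp)
    stats::uniroot(function(z) stats::pnorm(z) - pp, c(-10, 10),
                   tol = 1e-13)$root, numeric(1))
}
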