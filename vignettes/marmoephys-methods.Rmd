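---
title: "Methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(marmoephys)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Conventions

Times are seconds, double precision, session-relative (t = 0 at recording
start). All analysis windows are half-open `[start, end)`. Eye coordinates
are degrees of visual angle, +x right, +y up, polar angle counterclockwise
from +x — so a target at polar angle −72.7° sits in the lower-right
quadrant. On disk, raw traces are little-endian int16 with a
microvolts-per-count scale in a JSON sidecar (channel-major interleaving);
tables are comma-separated UTF-8 CSV with a header row. These are artifact
conventions, not claims about any original acquisition system; the loaders
reject missing sidecar keys and payload/metadata inconsistencies rather
than guessing.

## Preprocessing chain

The acquisition rate 24,414.0625 Hz is 25 MHz/1024, so resampling to
25 kHz is exactly rational: polyphase interpolation by 128 and decimation
by 125 with a Kaiser-windowed sinc whose polyphase branches are
individually normalized to unit DC gain (constants pass exactly; passband
flatness is tested below 0.01 dB at 1 kHz).

Re-referencing subtracts, per time sample, the median across the channels
of each shank from every channel of that shank; shanks are independent.
The median is idempotent here and removes any common-mode component
exactly.

Two spike-band designs are provided. `butter4_300_6000` is a 4th-order
Butterworth band-pass (prototype order 4, so 8 poles). For sessions with
optogenetic stimulation, `cheby2_40_300_8000` is a 40th-order Chebyshev
type II band filter with 200 dB stopband attenuation, realized as a
20th-order high-pass (edge 300 Hz) cascaded with a 20th-order low-pass
(edge 8 kHz): the total order and band are stated by the source analysis,
the high/low split is this package's design choice. All filters are
designed in zero-pole-gain form (analog prototypes, frequency prewarping,
bilinear transform), paired into second-order sections nearest-zero-first,
and applied **causally in a single pass**. Zero-phase filtering is not
claimed by the source; causal filtering keeps the order/attenuation
semantics literal. The group delay this introduces is documented, not
corrected — downstream tests therefore use phase-insensitive quantities.

MUA is full-wave rectification, a 6th-order Chebyshev II low-pass
(stopband edge 500 Hz, 50 dB), then decimation to 1 kHz keeping every 25th
sample starting at sample 0. Negative excursions from filter ringing are
clipped to zero: the series is an envelope. Up to the rectification the
chain is linear, so MUA scales linearly with input gain (tested to 1e-6
relative).

The filter design and SOS filtering code is implemented in the package
(no R signal-processing dependency is assumed); it is validated in the
tests against closed-form anchors: −3 dB at Butterworth band edges,
exactly −Rs at Chebyshev II stopband edges, unit DC gain, pole moduli
below 1, and a direct difference-equation oracle for the filtering kernel.

## Modulation statistics

A channel is *modulated* only when two criteria hold together: the
trial-averaged activity exceeds 3 baseline standard deviations in absolute
value (|z| > 3, with baseline mean and SD taken from the baseline samples
of the trial-averaged trace), and a two-sided Kolmogorov–Smirnov test
rejects at P < 0.05 between the baseline and stimulus windows. Window
defaults: visual −0.25–0 s vs 0–0.65 s; optogenetic −25–0 ms vs 0–25 ms.
The KS sample units are the **time samples of the trial-averaged trace**:
the tested object is the trial-averaged MUA and the two windows differ in
length (KS handles unequal n). Whether the original analysis pooled
per-trial values instead is ambiguous; both readings are implemented
(`ks_units = "trials"`), the trial-average reading is the default. Under
null simulations with independent samples the conjunction is conservative
(type-I ≤ 0.06 at α = 0.05, tested over 500 replicates); note that the
|z| > 3 arm alone is *not* a test — over 650 stimulus samples its null
exceedance probability is high — the distribution test carries the error
control.

Single units use per-trial spike counts in the stimulus window (matched to
the laser duration, 0–0.25 s or 0–0.20 s by session) compared across
conditions by a two-sided Wilcoxon rank-sum test, again combined with the
3-SD criterion on the trial-averaged rate.

PSTHs are 1 ms binned counts convolved with a unit-integral Gaussian
(truncated at ±4σ; σ = 10 ms for visual displays, 2 ms for optogenetic),
averaged across trials, in spikes/s. Autocorrelograms histogram all
pairwise lags at 0.33 ms resolution over ±50 ms (the lag span is this
package's choice; the source states only the bin width), remove the
central bin, and scale by the maximum. Orientation tuning is fit by least
squares with the 180°-periodic descriptor
R(θ) = b + a·exp(κ[cos 2(θ − θ_pref) − 1]) (multi-start Nelder–Mead over
θ_pref); the fit is descriptive, no significance is attached. Rate
stability smooths the session-long rate with σ = 2 s and excludes the
first and last 5 s.

## Spike-cluster curation

The sorter is an upstream producer; curation accepts a cluster only if all
three rules pass:

1. **Refractory violations** — fraction of inter-spike intervals below
   1.5 ms must not exceed 2.5 % ("more than" rejects, so exactly 2.5 %
   passes). The criterion is computed over ISIs; a per-spike accounting is
   available (`units = "spikes"`) since the source wording is ambiguous.
2. **Template similarity** — Pearson r ≥ 0.95 between the peak-channel
   mean waveform and at least one of 20 reference templates. The original
   manually selected templates are unavailable; the package ships a
   **synthetic** library of 20 biphasic shapes spanning trough-to-peak
   widths 0.3–1.2 ms (`waveform_template_library()`, with a CSV copy under
   `inst/extdata/waveform_templates_synthetic.csv`). Pearson r is
   scale-invariant, so no amplitude normalization is needed.
3. **Spatial spread** — fewer than 5 channels may exceed half the peak
   channel's amplitude. "Amplitude" is peak-to-trough of the trimmed-mean
   waveform per channel (the source does not define it; peak-to-trough is
   the conservative reading for biphasic spikes).

Mean waveforms are trimmed means with 5 % total exclusion, allocated
2.5 % per tail (the tail allocation is a package choice).

## Receptive-field mapping

Epochs span −100 to +180 ms around stimulus onset at 1 kHz (280 samples);
an epoch survives only if every eye sample stays inside the fixation
window. Epochs whose across-time SD exceeds 10× the median SD are noise
and removed. Per stimulus, a one-tailed paired t-test compares the
response-window mean against the baseline mean across epochs; a site is
modulated iff ≥ 3 wedge and ≥ 3 annulus stimuli are significant at
P < 0.01. The response window is the full post-onset epoch (0–180 ms) —
the source text defines the baseline but delegates the response window to
a prior method.

The map combines the wedge (polar-angle) and annulus (eccentricity)
marginal profiles **by their product** on a polar grid (24 × 12 by
default), min–max normalized to [0, 1], outlined at 0.2, with a
response-weighted centroid (circular mean over angle). The product rule is
a documented stand-in: the original back-projection lives in a cited prior
method whose details are out of reach here, so the acceptance tests check
centroid recovery on synthetic ground truth, not reproduction of published
RF shapes.

## Behavior and signal detection theory

Eye positions are smoothed with a 3 ms-SD Gaussian; speed is the magnitude
of the central-difference velocity; a saccade is a maximal run above
50 °/s, runs closer than 10 ms merged. The endpoint is the per-axis median
over the 25 ms after offset; saccades without a full 25 ms tail are
flagged endpoint-undefined. Go trials score a hit for saccade latency in
[50, 500) ms from target or laser onset, early below 50 ms, miss
otherwise; catch trials score a false alarm for any saccade within the
800 ms fixation requirement. Binomial CIs are Clopper–Pearson (the source
says only "binomial confidence intervals").

Catch trials outlast go trials, so the raw catch saccade rate
overestimates the false-alarm rate. The correction pairs, with
replacement, a random catch trial with a random go trial: a catch saccade
at time t (from background onset) counts as a false alarm only if t falls
inside the window where the paired go trial would have scored a hit. The
default pairs-per-replicate count is the expected catch count implied by
the 40 % catch fraction and the go-trial total; 1000 replicates are
averaged (rates and CIs). Catch trials are sampled from *all* catch
trials by default; the literal "catch trial with false alarm" reading is
available (`catch_source = "fa_only"`). The false-alarm timing reference
is background onset (the source does not state it). By construction the
corrected rate can only be at or below the raw rate.

Pairwise condition contrasts are 2×2 chi-squared tests with Yates
continuity correction, adjusted by Benjamini–Hochberg across the family of
five planned contrasts (high vs low, low vs low+opto, high vs high+opto,
opto-only vs catch, sham vs catch). This choice was verified against the
published adjusted p-values by reconstructing the count tables from the
printed totals and responder counts; the catch false-alarm count is the
printed corrected rate times the catch total, rounded, which leaves a
±1-count sensitivity in the third decimal of the two largest p-values.

d′ = Z(H) − Z(F) and c = −½[Z(H) + Z(F)] with Z the inverse Gaussian CDF;
rates of exactly 0 or 1 raise an error pointing to the 1/(2N) convention.
The bootstrap resamples the binary outcome vectors per condition
(equivalently, binomial draws), B = 10,000; CIs are the 5th/95th
percentiles; replicate rates hitting 0 or 1 are clamped by 1/(2N) so Z
stays finite. The contrast p-value is one-sided against sign reversal —
the proportion of replicate differences on the opposite side of zero from
the observed difference, floored at 1/B. The literal "equal to or larger
than the observed difference" wording would give ≈ 0.5 for any
self-centered distribution and cannot be meant; it is nevertheless
implemented (`p_method = "literal"`).

## The synthetic world

The generators state a world and the tests measure recovery in it; their
defaults are the recorded preparation's stated conditions wherever stated:
32-site shanks at 25 µm pitch, 25 kHz traces, 1 kHz eye tracking, laser
waveforms with 5 ms half-sine tapers starting and ending at exactly 0 mW,
40 % catch trials, go-trial onsets uniform 150–320 ms after background
onset, 800 ms catch fixation. Where the source states no value, one
realistic choice was made once:

- spike templates are a fixed biphasic shape with per-site amplitude
  ∝ exp(−d/40 µm), which gives the spatial-spread rule something to
  discriminate;
- response latencies are log-normal (median 0.25 s, σ_log 0.3) truncated
  to the hit window — unimodal, as reaction-time histograms are, with the
  exact shape unspecified by the source; these are placeholders and never
  acceptance-tested;
- false alarms are a homogeneous Poisson hazard from background onset,
  which yields a closed-form target for the correction-recovery test;
- fixational jitter is an Ornstein–Uhlenbeck process (SD 0.05°, τ 50 ms);
  saccade speed follows a Gaussian pulse truncated at ±2σ with
  σ = 3 + 0.5·A ms for amplitude A, normalized to exact displacement —
  the truncation makes speed clear the 50 °/s threshold within ~3 ms of
  pulse onset, which is what makes the detector's stated onset accuracy
  achievable, and peak speed exceeds 50 °/s for amplitudes ≥ 0.5°;
- a 0 Hz entry in a sinusoidal stimulus set renders as a constant plateau
  at peak power with tapered edges (a 0 Hz sinusoid is constant; the
  no-light control is a separate condition).

One deliberate departure from "rate proportional to the laser waveform":
the unit used for the autocorrelogram acceptance check
(`simulate_entrained_train()`) locks spikes to drive crests with sub-
millisecond jitter and a slow phase drift. An inhomogeneous Poisson rate
proportional to a sinusoid spreads pairwise lags over the full crest width
(several ms) and gives equal-height comb peaks at every multiple of the
period, so no amount of data localizes the global maximum to within one
0.33 ms bin of the period — the sharp, dominant first peak that criterion
describes (and that recorded entrained units show) implies tight locking
with phase diffusion, which is what the generator states. The recording
simulator keeps strict rate-proportionality for its opto units, and its
spectral entrainment test (power peak at 80 Hz) holds under that model.

What a green suite does *not* establish: reproduction of any published
neural site counts or RF shapes (those need the recorded data), realistic
LFP or photostimulation artifacts, reaction-time distribution tests, or
sorting quality beyond the three curation rules.

## Numerical choices and degenerate inputs

- Filters: SOS pairing nearest-zero-first; decimation keeps sample 0; MUA
  clipped at 0. An unstable design raises an error naming the design.
- Zero baseline variance raises an error naming the channel; a unit with
  zero spikes is "not modulated", not an error; a zero-variance waveform
  fails template QC with a reason rather than throwing.
- All-equal tuning rates return κ = 0, not an error. θ_pref is reported
  modulo 180°.
- Bundle round-trips are bit-identical for voltages on the stated int16
  grid and to 1e-9 s for times; arbitrary doubles are quantized to the
  int16 scale, which is the format's stated precision.
- Named RNG streams (`seeded_rng(seed, stream)`) decouple stages: the
  same session seed gives identical sessions regardless of how many
  bootstrap draws preceded them. Derived seeds stay below 2^31.

## Known limitations

- Whether the original spike-band filtering was causal or zero-phase is
  unstated; all quantitative checks here avoid phase.
- The RF map's product rule approximates an unavailable back-projection.
- The catch-sampling and bootstrap-p ambiguities noted above are resolved
  by documented defaults with the alternative behind a switch.
- The behavioral fixture reconstructs the published session from printed
  totals and responder counts; its latencies are placed, not recorded.
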