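---
title: "Vibroacoustic phase analysis of Veress needle insertion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vibroacoustic phase analysis of Veress needle insertion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veressva)
```

## The signal and its phases

During laparoscopic access a spring-loaded Veress needle is advanced through
the abdominal wall. Every tip–tissue interaction excites structure-borne
vibration that can be picked up at the needle's proximal end as a
vibroacoustic (VA) signal, sampled here at 16 kHz. Tissue–tissue punctures
(e.g. through a fascia) are rapidly damped by the next tissue layer; entry
into the peritoneal cavity instead releases the needle into free vibration,
so the spring-release "click" dominates every other event in the recording.
A cavity puncture decomposes into six phases:

1. **Ph1 — friction** between the needle's inner and outer cores, a
   band-limited (≈1800–7000 Hz) noise-like component that precedes the
   puncture; its duration depends on insertion velocity.
2. **Ph2 — tissue breakage**, a few-millisecond broadband burst at the
   instant the peritoneum gives way.
3. **Ph3 — attack**, the rapid energy rise as the spring tension releases.
4. **Ph4 — fast recovery** and
5. **Ph5 — slow recovery**, the bi-phasic decay of the click.
6. **Ph6 — post-puncture settling**, small residual vibration until the
   needle reaches a new stationary state.

The package implements the full chain: pre-processing, 400 ms event
extraction, continuous-wavelet time–frequency analysis, excitation
detection, phase segmentation, and per-event/cohort statistics — together
with a synthetic generator that produces such events with exact ground
truth, so the whole pipeline can be validated without access to cadaver
recordings.

## The synthetic generator and its calibration

`simulate_event()` builds a 400 ms segment: band-limited friction noise
ending at the burst onset (segment centre), a white-noise burst under a
half-sine envelope, and — 3.5 ms after the burst onset — a click with a
1.5 ms broadband attack followed by damped sinusoid carriers (1200, 2700,
4100, 6300 Hz). Gaussian background noise (RMS 0.005) is added throughout.
The defaults are the study conditions the analysis is validated against and
are not tuning knobs:

* **Component energies** (sums of squared samples): click 160, burst 8,
  friction RMS 0.05. At the median friction duration of ~20 ms the friction
  energy is 0.05² × 0.020 s × 16000 Hz = 0.8, so the click-to-burst and
  click-to-friction ratios are ×20 and ×200 *by construction* — the cohort
  medians the pipeline is expected to recover.
* **Friction duration** is log-normal on the millisecond scale (log-mean
  3.0, log-sd 0.6): median `exp(3) ≈ 20` ms with a right-skewed spread, the
  shape expected from a velocity-dependent duration. Samples are clamped at
  190 ms so the layout always fits the window (probability ≈ 7×10⁻⁵).
* **Latency** (burst onset → click onset) is fixed at 3.5 ms, inside the
  reported < 5 ms bound with minimal dispersion, since it reflects only the
  needle's internal mechanics.
* **Click recovery** is bi-exponential in energy. The squared-amplitude
  envelope is proportional to `(w/τf)·e^(−t/τf) + ((1−w)/τs)·e^(−t/τs)`
  with τf = 5 ms, τs = 35 ms and **w = 0.95 the fraction of total click
  energy in the fast term**. With this parameterization the cumulative
  post-peak energy is exactly `w(1−e^(−t/τf)) + (1−w)(1−e^(−t/τs))`, and
  `click_recovery_time()` gives the closed-form recovery times
  13.3 / 19.1 / 34.0 ms at the 90/95/98 % thresholds — the oracle used in
  the tests. (Reading w as an instantaneous envelope weight instead would
  triple these times; only the energy-fraction reading reproduces the
  13/20/35 ms profile a single exponential cannot.)
* **Burst suppression** (`ph2_present = FALSE`) zeroes the burst without
  reallocating its energy — the simplest mechanism for punctures whose
  breakage instant is not discernible, giving exact expected presence
  counts (141 of 154 in the reference cohort of `porcine_cohort_spec()`).

`simulate_insertion()` embeds one such event (iff the insertion reaches the
cavity) in a 5–15 s recording with 1–3 rapidly damped tissue transients
(amplitude ≤ 0.15, amplitude decay constants of 0.5–1.5 ms — within the
"few milliseconds" damping regime and clearly separated from the click's
tens-of-milliseconds decay). The annotation time is the true burst onset
(click onset when suppressed), mimicking an annotator marking the perceived
loss of resistance.

What the generator does **not** emulate: sensor/mechanical coloration,
non-Gaussian or non-stationary backgrounds (handling noise, speech), skin
or fascia punctures with partial damping, velocity-dependent friction
spectra, or multiple puncture attempts per recording. Passing tests
therefore demonstrate correctness of the signal-processing chain under the
stated phenomenology, not clinical performance on real recordings.

## Pre-processing

`preprocess()` composes three stages, each length-preserving:

* **DC removal** subtracts the sample mean.
* **Spectral gating** (`spectral_gate()`): Hann STFT (frame 1024, hop 256),
  per-frequency-band noise floor at the 25th percentile of the band's own
  magnitude distribution (events are temporally sparse, so the percentile
  sees noise), threshold at 3× the floor, soft mask smoothed over 3×3
  (time × frequency) bins, attenuation bounded at 30 dB. The floor estimate
  is median-filtered across frequency (15 bins) so a narrowband stationary
  component does not inflate its own floor and gate itself. The gains never
  exceed 1; the overlap-add resynthesis of the masked spectrogram can
  redistribute a fraction of a percent of magnitude between bins, which is
  why the non-amplification guarantee is stated (and tested) at the mask
  level plus output RMS.
* **DWT band filtering** (`dwt_filter()`): ten-level Daubechies-4
  decomposition, reconstruction from detail levels 1–5 only (the half-bands
  above ≈250 Hz at 16 kHz), removing baseline trend and emphasizing the
  high-frequency content of tip–tissue interactions. The transform is the
  periodized orthogonal DWT after reflection padding to a multiple of 2¹⁰,
  so reconstruction with all bands kept is exact to machine precision. The
  wavelet order and kept scales are declared package defaults, configurable
  in `dwt_filter_params()`.

## Event analysis

`extract_segment()` takes the `round(0.4 fs)` samples centred on the
annotation — centring maximizes pre/post context around the puncture.
`compute_cwt()` provides the scalogram: analytic Morlet (ω₀ = 6), log-spaced
frequency grid from 100 Hz to fs/2 at 12 voices/octave, FFT-accelerated
with zero-padding to twice the segment length; a brute-force inner-product
oracle defines correctness in the tests.

`detect_excitations()` scans a 2 ms / 0.5 ms short-time RMS envelope,
thresholds at median + 8 MAD, and keeps local maxima separated by 300 ms.
A peak is a *cavity candidate* if it dominates the largest envelope outside
its own refractory window by ≥ 3× and its decay (time to fall below 20 % of
the peak or back into the noise band, whichever is higher) lasts ≥ 5 ms.
Comparing against the whole residual envelope rather than only other
accepted peaks makes the rule robust to recordings whose transients are
largely removed by the gate.

`segment_phases()` operationalizes the phase boundaries; where the
qualitative description leaves a criterion open, the choice is declared
here and exposed in `segmentation_params()`:

* the **attack peak** is the maximum of a fine 0.25 ms RMS envelope; the
  fine envelope is essential because the gap between burst end and click
  onset is only ~0.5 ms and a 2 ms envelope cannot resolve it;
* **Ph3 onset** is the last rising crossing of 5 % of the peak envelope
  before the peak;
* **Ph4/Ph5/Ph6 boundaries** sit at the 90 % and 98 % points of the
  cumulative post-peak energy, Ph6 ending when the envelope returns below
  the segment noise floor + 3 MAD (the 90 % point aligns the fast-recovery
  phase with the first reported recovery threshold);
* **Ph2** is searched in the 15 ms before the Ph3 onset on a 1 ms envelope:
  a run above `max(6 × window median, 10 % of the peak envelope)` whose
  scalogram column is broadband (≥ 2 octaves within −12 dB of the column
  maximum). The composite gate is needed because friction (RMS 0.05) sits
  exactly at a naive 5 %-of-peak level; the onset is then refined to the
  envelope minimum at the foot of the rise, which keeps burst energy out of
  the adjacent friction interval;
* **Ph1** is the last run (gaps ≤ 2 ms bridged, duration ≥ 5 ms) of the
  1800–7000 Hz band envelope above `max(3 × band floor, 5 % of the band
  maximum)`, searched before the Ph2 (or Ph3) onset. The band filter is
  applied to the pre-burst portion only — filtering the whole segment would
  leak sinc tails of the click backwards across the friction region — and
  the floor is the 10th percentile of that band envelope. The 5 % relative
  term keeps the gate meaningful on noise-free signals, where Gibbs
  ringing at the friction edges is otherwise comparable to a vanishing
  floor.

## Metrics and cohort summaries

Phase energies are sums of squared samples over the phase interval. **E3,
the click energy used in the ×20/×200 comparisons, spans Ph3 onset through
the Ph6 offset** — the whole click component (attack plus both recovery
phases); the attack alone carries under a tenth of the click's energy and
could not reproduce the by-construction ratios. Ratios are reported both as
percentages of E3 (Fig.-style convention) and as fold changes E3/E1, E3/E2.
`recovery_time()` integrates post-peak energy to the segment end; the
trailing background noise contributes ~5×10⁻⁴ of the click energy and is
negligible. Metrics undefined for an event (latency and E2 when no burst is
discernible, friction metrics when no sustained friction run exists) are
NA and excluded from cohort statistics — never zero-filled.

Cohort summaries use quartiles by linear interpolation of order statistics
(R type 7), whiskers at the most extreme points within 1.5 IQR, outliers
beyond; the convention matters for boxplot statistics and is therefore
fixed and oracle-tested.

## Numerical choices and degenerate inputs

All envelopes are cumulative-sum moving RMS (exact, O(n)). The band filter
is a zero-phase FFT brick-wall. Segments with no envelope peak above
6 × noise median + 8 MAD raise a typed `veressva_not_event` condition;
zero post-peak energy and absent-phase energies raise
`veressva_undefined_metric`. All randomness flows from explicit seeds
(`withr::with_seed`); cohorts derive per-recording child seeds by a counter
scheme, so results are independent of generation order. WAVE I/O supports
16-bit PCM (clipping out-of-range amplitudes with a warning) and 32-bit
float (lossless; synthetic clicks exceed full scale by design, since
energies are calibrated in sample² units).

## Validation problem sizes

The shipped tests segment a 154-event cohort (13 burst-suppressed), run
detection end-to-end on 154 simulated insertions, and check the phase
ordering invariants on 1000 randomized events — the reference cohort scale,
chosen so the suite exercises the same sample sizes as the summary
statistics it checks. The acceptance script (`scripts/acceptance.R`)
regenerates these cohorts from a command-line seed and recomputes every
headline statistic from scratch.

## Known limitations

* The Ph2 broadband criterion and the Ph1 onset/offset rules are
  operational definitions; the underlying phenomenology gives no exact
  thresholds, so absolute counts near the gate boundaries can shift by an
  event or two with the noise realization.
* The spectral gate assumes temporally sparse events; long sustained
  broadband activity would raise the estimated floor and be partially
  gated.
* Friction-like artifacts from other tissue structures are not simulated;
  distinguishing them from cavity-entry friction is out of scope.
* Detection operates offline on whole recordings; no streaming mode.
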