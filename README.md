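# veressva

Vibroacoustic analysis of Veress needle insertion signals.

## The problem

Establishing laparoscopic access with a spring-loaded Veress needle relies
on the surgeon's subjective feel for the "click" of cavity entry, and
misplacement is a major source of complications. The structure-borne
vibroacoustic (VA) signal at the needle's proximal end carries an objective
signature of that moment: tissue–tissue punctures are rapidly damped,
whereas entry into the peritoneal cavity releases the needle into free
vibration, producing an excitation that dominates everything else in the
recording. `veressva` is for signal-processing and biomedical-engineering
work on such recordings: it implements the full offline analysis chain and
a calibrated synthetic-signal generator so the chain can be developed and
validated without access to cadaver data.

## What it computes

A cavity puncture event decomposes into six phases: inner/outer-core
friction (Ph1, band-limited to ≈1800–7000 Hz), peritoneum tissue breakage
(Ph2, a short broadband burst), the click attack (Ph3), fast and slow
recovery (Ph4, Ph5) and post-puncture settling (Ph6). The pipeline is

1. **pre-processing** — DC removal, spectral-gating noise reduction
   (per-band percentile noise floor, soft mask, ≤30 dB attenuation), and a
   ten-scale Daubechies-4 DWT filter keeping detail levels 1–5;
2. **event analysis** — 400 ms segment extraction around the annotated
   puncture instant, analytic-Morlet CWT scalograms (100 Hz–8 kHz,
   12 voices/octave), excitation detection on a short-time RMS envelope
   (median + 8 MAD threshold, 300 ms refractory, dominance and
   decay-duration rules for cavity candidates), and six-phase segmentation
   from envelope and cumulative post-peak energy criteria:
   Ph4 = peak → t(0.90), Ph5 = t(0.90) → t(0.98);
3. **metrics** — phase energies E = Σ x², energy ratios E3/E1 and E3/E2,
   friction duration, Ph2→Ph3 latency, recovery times t(F) with
   cumulative post-peak energy thresholds F ∈ {0.90, 0.95, 0.98}, total
   event duration, and cohort count/boxplot summaries.

The generator (`simulate_event`, `simulate_insertion`, `simulate_cohort`)
produces events with exact ground truth, calibrated so that the cohort
medians are known in closed form: energy ratios ×20 and ×200, friction
median 20 ms (log-normal), latency 3.5 ms, and a bi-exponential click
energy envelope (τ = 5/35 ms, fast-energy weight 0.95) whose 90/95/98 %
recovery times solve `w(1−e^(−t/τf)) + (1−w)(1−e^(−t/τs)) = F`, giving
13.3 / 19.1 / 34.0 ms.

## Worked example

```r
library(veressva)

ev <- simulate_event(sim_event_config(), seed = 7)
pb <- segment_phases(ev$segment)
print(pb)
#> <va_phase_bounds> attack peak at 0.2057 s
#>  phase     onset    offset present
#>    ph1 0.1203125 0.1998750    TRUE
#>    ph2 0.1999375 0.2024375    TRUE
#>    ph3 0.2036875 0.2057500    TRUE
#>    ph4 0.2057500 0.2192500    TRUE
#>    ph5 0.2192500 0.2430000    TRUE
#>    ph6 0.2430000 0.2511250    TRUE

m <- compute_event_metrics(ev$segment, pb)
cat(sprintf("E3/E2 = %.1f   E3/E1 = %.1f\n", m$fold_3_to_2, m$fold_3_to_1))
#> E3/E2 = 20.1   E3/E1 = 49.0
```

The friction phase here lasted 79.6 ms (a draw from the right-skewed
log-normal; that is why this single event's E3/E1 is 49, not the cohort
median of ≈200), the burst-to-click latency was 3.75 ms, and the measured
recovery times were 13.5 / 19.9 / 37.2 ms at the 90/95/98 % energy
thresholds — against closed-form targets of 13.3 / 19.1 / 34.0 ms.

Detection on a whole insertion recording:

```r
out <- simulate_insertion(sim_event_config(), seed = 11, reached_cavity = TRUE)
exc <- detect_excitations(preprocess(out$recording))
print(exc)
#>   event_time peak_envelope decay_ms is_cavity_candidate
#> 1     1.9040    0.02410174      2.5               FALSE
#> 2     3.4295    1.21998521     16.5                TRUE
#> 3     5.7405    0.03772009      2.0               FALSE
```

The two rapidly damped tissue transients are reported but rejected as
cavity candidates; the click at 3.4295 s is flagged, within a millisecond
of the true attack peak at 3.4284 s.

Cohort-scale work goes through `pipeline_config()` / `run_simulate()` /
`run_analyze()` (or the `inst/cli/veressva` script), which write WAVE +
CSV cohorts and per-event/cohort report tables.

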