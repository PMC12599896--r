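# tremortrack

Real-time phase tracking of Parkinsonian rest tremor from wrist-worn
triaxial accelerometry, with phase-locked stimulation triggering — an R
re-implementation of an adaptive wearable phase-tracking system, from the
streaming estimator up to the in-clinic experimental protocol and its
offline validation statistics.

## The problem

Rest tremor (3–7 Hz in Parkinson's disease) can be modulated by electrical
stimulation at the wrist delivered at specific angles of the tremor cycle.
That requires estimating the instantaneous tremor phase in real time from
accelerometry — hard, because the dominant movement axis and the tremor
center frequency both drift. The package implements:

- **Phase tracker** — a noise-driven harmonic oscillator in state-space
  form. A phasor (a, b) rotates at a fixed reference frequency f_c; each
  sample the prediction error e = x_in − a, weighted by a gain G ∈ (0, 1)
  (default 0.25, the empirically optimal value), corrects the real
  component:

      e  = x_in − a
      a* = a + G e
      Φ  = atan2(b, a*) ,  M = √(a*² + b²)
      (a, b) ← R(2π f_c / f_s) (a*, b)

- **Adaptive bank** — 21 streams (3 axes × f_c ∈ {2…8} Hz) run in
  parallel; every 20 s the dominant axis (largest 10-s moving average
  μ_axis of |amplitude|) and best frequency (smallest 10-s moving average
  μ_error of |e|) are locked for the next stimulation block.
- **Preprocessing** — streaming 0.1 Hz order-2 Butterworth high-pass
  (SOS, direct form I) for offset removal; zero-phase 1–9 Hz band-pass
  for the offline oracle.
- **Trigger logic** — stimulation fires when the locked phase falls within
  the error budget f_c/f_s·360° of the target phase (current or previous
  sample), then emits 5 pulses at f_s/2 = 104.015 Hz.
- **Protocol** — 10-min baseline; random search (10 blocks × 8 shuffled
  states: phasic 0°…300°, open-loop, sham; 10 s on / 10 s off); 1-min
  baseline; 10-min continuous stimulation at the most suppressive state.
- **Offline analysis** — band-pass + Hilbert oracle phase/envelope,
  wrap-corrected phase error, median instantaneous frequency (0.1 Hz
  resolution), per-trial severity change, state–amplitude profiles with
  Bonferroni-corrected sign-flip resampling limits, rank-sum envelope
  comparison.
- **Synthetic tremor generator** — scenarios with per-axis envelopes,
  frequency trajectories, cessation intervals, DC offsets and pink/brown
  noise, with per-sample ground truth (phase, dominant axis, frequency).

## Worked example

```r
library(tremortrack)

sc  <- read_scenario(system.file("extdata", "example_scenario.yaml",
                                 package = "tremortrack"))
rec <- gen_tremor_record(sc)          # 60 s, y-dominant 4 Hz + pink noise
trk <- track_record(rec)              # high-pass -> 21 streams -> self-tuning
glance(trk)
#>   n_samples fs_hz duration_s n_streams     G n_selections final_axis final_fc_hz
#> 1     12482  208.       60.0        21  0.25            2 y                    4

trk$selections[, 1:6]
#>   time_s axis  fc_hz mu_axis_x mu_axis_y mu_axis_z
#> 1   20.0 y         4     0.136     0.381    0.0758
#> 2   40.0 y         4     0.146     0.384    0.0651

orc <- oracle_phase_envelope(rec$ay_g, attr(rec, "fs"))
phase_error(tidy(trk)$phi_deg[rec$time_s > 5], orc$phase_deg[rec$time_s > 5])
#> phase error vs Hilbert oracle: 10.32 +/- 9.73 deg
median_instantaneous_frequency(orc, 208.03)
#> [1] 4
error_budget(4)
#> [1] 6.920156
```

The bank locks onto the true axis (y) and frequency (4 Hz) at every
selection instant. The ~10° mean phase error against the zero-phase oracle
is dominated by the pink noise below the tremor band, which the causal
pipeline passes but the oracle's 1–9 Hz band-pass removes — see the
methods vignette (`vignettes/tremor-phase-tracking.Rmd`) for why this gap
is intrinsic to the streaming estimator.

`autoplot(trk)` shows the locked selection, envelope and phase;
`autoplot(profile_significance(trials))` draws the state–amplitude profile
with its corrected limits; `plot_phase_alignment(result)` shows target
versus actual stimulation phases.

A thin command-line front end mirrors the library:

```sh
Rscript inst/cli/tremortrack.R simulate --scenario scenario.yaml --out rec.csv
Rscript inst/cli/tremortrack.R track    --in rec.csv --out-prefix trk
Rscript inst/cli/tremortrack.R protocol --in rec.csv --out-prefix prot --seed 1
Rscript inst/cli/tremortrack.R analyze  --in rec.csv --out-prefix ana
Rscript inst/cli/tremortrack.R validate --seed 1
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package: the phase-trigger
error budget at the top of the frequency grid (f_c = 8 Hz, f_s = 208.03 Hz),
and the difference in mean wrap-corrected phase error between high-pass
and band-pass tracker inputs on a 2–8 Hz noisy-sinusoid suite (pink and
brown noise at SNR 3, 10 seeds × 60 s per condition, scored against the
band-pass + Hilbert oracle with 5 s warm-up excluded). Results are written
as JSON to `--out`; `--seed` derives every noise seed used.
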