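# gaitevents

Automatic detection of gait events — touchdown (TD, foot contact) and liftoff
(LO, toe off) — in regular and perturbed (slip/trip) walking, for researchers
in biomechanics and movement analysis who currently annotate perturbed trials
by hand. Threshold rules on the vertical ground reaction force work for clean
steady-state gait but fail on perturbed trials: recovery steps land off the
force plates, arrive at unpredictable times, and aborted steps drag along the
floor without a clean liftoff.

The package treats event detection as sequence labelling. Per trial, a
multichannel time series at 120 Hz (3 s, 360 frames) — ground reaction
forces, marker trajectories, or sagittal segment angles — is mapped by a
two-layer **bidirectional GRU** to a per-frame trace whose peaks mark events.
Targets encode TD as +1, LO as −1 and non-events as 0, smoothed with a
double-gamma (HRF-style) kernel normalized so an isolated event peaks at
exactly ±1 at the event frame. Each GRU cell follows

    z_t = σ(W_z x_t + U_z h_{t−1} + b_z)
    r_t = σ(W_r x_t + U_r h_{t−1} + b_r)
    h̄_t = tanh(W_h x_t + U_h (r_t ⊙ h_{t−1}) + b_h)
    h_t = (1 − z_t) ⊙ h_{t−1} + z_t ⊙ h̄_t

with forward and backward passes concatenated per frame, followed by batch
normalization, dropout and a per-frame dense head. Training minimizes the
weighted squared error `L = Σ λ_t (y_t − ȳ_t)²` with `λ_t = 1 + 9|ȳ_t|`
(event frames weigh 10× the abundant non-event frames) using Adam, batch 64,
early stopping on validation loss (patience 3, best weights restored).
Separate models are trained for TD and LO. Predicted traces are decoded by
constrained peak finding (height > 0.3, separation > 250 ms) and scored
against ground truth with 50 ms and 30 ms tolerances.

Because no public dataset pairs perturbed-walking signals with event
annotations, the package includes a parametric simulator of regular, slip and
trip trials with exactly known events — including backward foot slides,
delayed recovery steps, elevated post-trip swings and aborted steps with foot
dragging — so the whole pipeline is testable end to end.

## Worked example

Simulate a 270-trial cohort (30 subjects × {regular, slip, trip} × 3
trials), train marker-based TD and LO detectors (hidden size 32) and score
the held-out 20% — a few minutes on one CPU:

```r
library(gaitevents)

cfg <- run_config(
  dataset = "marker",
  sim     = synthetic_config(),            # 30 subjects x 3 types x 3 trials
  train   = train_config(hidden_units = 32L),
  seed    = 42)
res <- run_pipeline(cfg)
print(res)
#> <pipeline_result> dataset=marker, 270 trials (54 test)
#>   TD: mean error 6.62 ms, within_50ms = 99.3%, within_30ms = 97.1%
#>   LO: mean error 5.71 ms, within_50ms = 100.0%, within_30ms = 100.0%

head(subset(res$results$TD$per_event, trial_type == "slip"), 4)
#>       trial_id trial_type true_frame detected_frame error_ms
#> 4 s001_slip_01       slip         18             17 8.333333
#> 5 s001_slip_01       slip        150            149 8.333333
#> 6 s001_slip_01       slip        273            272 8.333333
#> 7 s001_slip_02       slip         74             75 8.333333
```

The summary lines read: over the 54 held-out trials, detected touchdowns
deviate from ground truth by 6.6 ms on average, 99.3% fall within the 50 ms
tolerance used for real-time control applications and 97.1% within the
stricter 30 ms tolerance; `per_event` lists every matched event with its
error in milliseconds (one 120 Hz frame = 8.33 ms). These synthetic-cohort
numbers show the pipeline is coherent end to end; they do not measure
performance on real perturbed gait (see the vignette's limitations).

Lower-level entry points: `simulate_trial()` / `simulate_dataset()`,
`lowpass_bidirectional()`, `segment_angles()`, `encode_raw()` /
`hrf_kernel()` / `smooth_targets()`, `train_bigru()`, `find_event_peaks()`,
`match_events()`, `detection_metrics()`, and `write_trial()` /
`read_trial()` for the CSV trial store. A thin command-line front end lives
at `inst/cli/gaitevents.R` (`simulate` and `run-all` subcommands).

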