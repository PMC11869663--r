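---
title: "Detecting gait events in perturbed walking with bidirectional GRUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gait events in perturbed walking with bidirectional GRUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Touchdown (TD, foot contact) and liftoff (LO, toe off) delimit every stride and
underlie all spatiotemporal gait measures: step time, stance fraction, reaction
time after a balance perturbation. For regular treadmill or walkway gait these
events are read off the vertical ground reaction force (GRF) with a simple
threshold. Slip- and trip-perturbed walking breaks that recipe: feet half-land
or cross-land off the force plates, recovery steps arrive at unpredictable
times, and aborted steps drag along the floor without a clean liftoff. In
practice perturbed trials are annotated by hand, minutes per gait cycle.

`gaitevents` frames the task as sequence labelling. Each 3-second trial is a
multichannel time series at 120 Hz (360 frames); per frame the model regresses
a continuous trace whose peaks mark events. A bidirectional GRU is a natural
fit: the signature of a touchdown involves both the approach (foot descending)
and the aftermath (loading response), so each frame benefits from context in
both temporal directions. Separate models are trained for TD and for LO, and
three input representations are supported: `grf` (3 force channels),
`marker` (16 position channels: heel, toe, knee, hip of both limbs, AP and
VT axes) and `angle` (6 sagittal segment angles: foot, shank, thigh of both
limbs).

## From annotations to regression targets

Events are first encoded per frame: TD as $+1$, LO as $-1$, all other frames
$0$ (`encode_raw()`). The per-event models use a single positive channel each
(`td_only` / `lo_only`), so the same positive-peak decoder serves both. A bare
impulse among 359 zeros is a hopeless regression target — the label mass is
too imbalanced — so the impulse train is convolved with a smooth
double-gamma kernel (`hrf_kernel()`), the shape family used for hemodynamic
responses, rescaled here to gait time-scales:

* `peak_delay_s = 0.25`, `dispersion_s = 0.08` — the main bump spans roughly
  ±0.2 s around the event, comparable to the loading/unloading transients it
  should absorb;
* `undershoot_delay_s = 0.6`, `undershoot_ratio = 0.1` — a shallow negative
  tail that sharpens the peak against its surroundings;
* `kernel_len_s = 1.5` — support long enough to contain the undershoot.

Two normalization decisions matter downstream. The kernel is *shifted* so its
maximum sits at lag zero and *rescaled* so that maximum is exactly 1: an
isolated event then smooths to a peak of exactly 1 at the event frame, so the
decoder's peak positions are event times with no systematic lag. Overlapping
kernels are summed and clipped to $[-1, 1]$; within a trial, consecutive
same-type events sit ~1 stride apart, so only the small undershoot tails
overlap and peaks stay within a few hundredths of 1. The LO model encodes its
events as $+1$ rather than $-1$ so the decoder's positive height threshold
applies unchanged; nothing in the loss or architecture distinguishes the sign.

## The model

Each GRU cell follows the standard gating equations
$z_t = \sigma(W_z x_t + U_z h_{t-1} + b_z)$,
$r_t = \sigma(W_r x_t + U_r h_{t-1} + b_r)$,
$\bar h_t = \tanh(W_h x_t + U_h(r_t \odot h_{t-1}) + b_h)$,
$h_t = (1-z_t)\odot h_{t-1} + z_t \odot \bar h_t$, starting from $h_0 = 0$.
Some write-ups print the reset gate with $U_r$ applied to $x_t$; that variant
is reachable via `gru_step(..., literal_reset_gate = TRUE)` but the standard
recurrent form is the default — with $U_r x_t$ the reset gate ignores the
state entirely, which defeats its purpose and only type-checks when input and
hidden sizes coincide. A bidirectional layer runs one GRU forward and one
backward over the sequence and concatenates the states per frame
(`bigru_sequence()`).

The full network (`bigru_model()`) stacks two bidirectional layers, then a
per-feature batch-normalization layer, dropout, and a per-frame affine map to
a scalar. There is no output nonlinearity: targets live in $[-1,1]$ and the
decoder thresholds at 0.3, so a squashing function would only compress the
gradient. Batch normalization is computed per feature over all frames of all
trials in the batch while training; inference uses running statistics,
accumulated as a cumulative average over the first updates and an
exponential moving average (momentum 0.1) thereafter — with only a few
batches per epoch a plain moving average would lag the weights for many
epochs, which matters because early stopping reads a validation loss
computed from those running statistics.

Training (`train_bigru()`) minimizes the weighted squared error
$L = \sum_t \lambda_t (y_t - \bar y_t)^2$ with
$\lambda_t = 1 + \alpha\,|\bar y_t|$ and $\alpha = 9$: frames at an event
peak weigh 10× a non-event frame, countering the ~100:1 frame imbalance
while keeping every frame in the objective. The exported `weighted_mse()` is
the exact sum; the optimizer works with the per-frame mean of the same
quantity, a constant rescaling absorbed by the learning rate. Optimization is
mini-batch Adam (batch 64 trials, learning rate $10^{-3}$), at most 100
epochs, early-stopped when the validation loss fails to improve for 3
consecutive epochs, restoring the best-validation weights. Hidden size
(64/direction by default), dropout (0.2) and the learning rate are exposed in
`train_config()`; they are conventional values for a model of this size, not
the product of a search. Input weights are Glorot-uniform and recurrent
weights orthogonal, the customary initialization for gated recurrent
networks; it noticeably stabilizes the first epochs, during which a
badly-conditioned start can inflate the validation loss long enough to
trigger the patience rule on a still-untrained model. Input channels are z-scored with training-set
statistics, stored in the detector and re-applied at prediction.

Trials are split 80/20 into training and test, with 20% of the training
portion held out for validation. The default shuffles trials; an optional
`split_by = "subject"` keeps every subject's trials in one partition for a
stricter generalization test.

The reference implementations (`gru_step()`, `bigru_sequence()`,
`bigru_forward()`) are plain double-precision R and define the semantics; the
training loop runs on an equivalent single-precision RcppArmadillo batch
engine (`src/bigru.cpp`) whose forward pass is tested against the reference.
Single precision is the customary arithmetic for training networks of this
size and roughly halves time and memory; parameters, gradients and the Adam
state remain double on the R side.

## Decoding and evaluation

`find_event_peaks()` decodes a predicted trace into event frames: interior
local maxima (plateaus contribute their midpoint frame, floored), discarding
peaks below height 0.3, then greedy suppression in descending height so
surviving peaks are at least 250 ms apart (30 frames at 120 Hz) — 250 ms
being about the shortest interval physiology allows between consecutive gait
events even in perturbed stepping. Ties in height break toward the earlier
frame so decoding is deterministic.

`match_events()` pairs detections with ground truth one-to-one, greedily by
ascending absolute frame difference. Unmatched true events (misses) count
against the tolerance accuracies but are excluded from the mean error;
unmatched detections are reported as extras. All four counts are returned so
alternative conventions can be recomputed from the per-event table.
`detection_metrics()` reports mean ± SD of matched errors in milliseconds and
accuracy at 50 ms and 30 ms — the share of *all* true events detected within
tolerance.

## The synthetic cohort

No public dataset pairs perturbed-walking signals with event annotations, so
the package ships a parametric simulator (`simulate_trial()`,
`simulate_dataset()`) that fabricates trials with *exactly known* events —
every downstream stage is tested against construction-time truth rather than
re-derived labels.

Each subject draws a cadence (95–120 steps/min) and step length
(0.55–0.75 m) once, so trials within a subject correlate. A trial is a
3-second window with a uniformly random gait phase. The left foot (the limb
taking the first recovery step after a perturbation, and the only limb
annotated) generates:

* **GRF** (600 Hz, body-weight fractions): per stance, a double-bump vertical
  profile — a powered-sine envelope $\sin(\pi\phi)^{0.25}$ modulated by
  $1 + 0.15\cos 4\pi(\phi - 0.25)$ — with braking-then-propulsion AP and a
  small ML component. The sharp envelope makes loading onset crisp enough
  that a 5%-body-weight threshold crossing recovers each event within one
  600 Hz frame on noiseless trials, which is the simulator's own acceptance
  oracle. A plain raised-cosine bump was rejected for this reason: its zero
  slope at stance onset leaves the threshold crossing several frames late.
* **Markers** (120 Hz, meters): heel and toe planted during stance, swinging
  forward with a smooth-step profile and sinusoidal height between footfalls;
  ankle, knee and hip ride on the feet and a constant-speed pelvis. Heels
  touch the floor exactly at TD and toes leave exactly at LO, which is the
  kinematic cue the models learn.
* **Perturbations**: a *slip* starts at a right-foot touchdown — the stance
  foot slides backward (0.12 m by default) and the left recovery touchdown is
  delayed by 80–250 ms; with probability `abort_prob` the recovery step is
  aborted and the foot drags, leaving the vertical GRF above zero through the
  nominal swing. A *trip* strikes the left foot mid-swing: the remaining
  swing is elevated (0.10 m) and the touchdown delayed by 60–200 ms. Delays
  shift all subsequent events, and schedules violating the 250 ms minimum
  event spacing are rejected rather than silently repaired.

Gaussian noise (SD 0.02 body weights on forces, 3 mm on markers) is added
last, and vertical forces are clamped non-negative.

What the simulator does **not** emulate: soft-tissue and impact transients,
marker occlusion/mislabeling, cross-landing on the contralateral plate,
harness loads, mediolateral marker motion, and the full diversity of human
recovery strategies. Passing the end-to-end check on synthetic data therefore
demonstrates that the pipeline is implemented coherently — targets, model,
decoder and metrics agree — not that the trained weights transfer to real
perturbed gait.

## Preprocessing details

GRF channels are low-pass filtered at 50 Hz and kinematics at 12 Hz, both
with a fourth-order Butterworth applied forward and backward (zero phase; two
−3 dB passes leave half amplitude at the cutoff). Edges use odd-reflection
padding of three filter lengths with steady-state initial conditions, so a
constant signal passes through exactly. The filtered 600 Hz force channels
are decimated by keeping every 5th sample — the 50 Hz filter already
prevents aliasing at the 120 Hz target rate. Missing marker samples are
filled from the temporally nearest observation before filtering, ties
breaking toward the earlier sample. Segment angles are four-quadrant
arctangents of the segment vectors (heel→toe, ankle→knee, knee→hip) against
the horizontal, in degrees; coincident marker pairs are an error naming the
frame rather than a NaN.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use a 30-subject cohort (3 trials
per type per subject, 270 trials; ~420 annotated left-side events per event
type) with hidden size 32 — ample for signals this clean, and the training
run converges in a few minutes per model on one CPU. Batch-norm uses
$\varepsilon = 10^{-5}$; Adam uses the customary $(\beta_1, \beta_2) =
(0.9, 0.999)$. All randomness (subject parameters, trial phases, weight
initialization, shuffling, dropout) flows from explicit seeds, and identical
seeds reproduce identical results bit-for-bit on one device.

## Known limitations

* The simulator's stereotyped waveforms make the detection task easier than
  real perturbed gait; reported synthetic accuracies are an upper bound.
* Only the left limb carries force data and annotations; the right limb
  contributes kinematic context only.
* The matching convention (greedy one-to-one, misses excluded from mean
  error) is one of several defensible choices; the per-event table lets a
  user recompute alternatives.
* Single-trial batch normalization at inference relies on running statistics
  from training; applying a detector to signals with a very different
  amplitude distribution requires re-estimating the channel z-scores.
* Early stopping with patience 3 operates at epoch granularity. On small
  cohorts (roughly under ~150 trials, i.e. two or three batches per epoch)
  the validation loss is noisy enough that training can halt during an early
  transient, leaving an underfit detector; at the 270-trial study scale the
  shipped defaults train to convergence reliably. For small datasets raise
  `patience_epochs` or lower the learning rate.
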