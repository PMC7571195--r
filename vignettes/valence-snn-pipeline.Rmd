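---
title: "Classifying emotional valence with a spiking reservoir: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying emotional valence with a spiking reservoir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikecube)
```

## The problem and the model

`spikecube` classifies binary emotional valence (unpleasant vs pleasant)
from multimodal recordings of a person watching an emotional stimulus: ten
facial landmark-distance features and six peripheral physiological channels
(heart-rate variability, respiration variability and depth, skin
temperature, galvanic skin response, pupil diameter). The classifier is a
brain-inspired spiking neural network: feature time series are turned into
spike trains, injected into a three-dimensional recurrent reservoir of
leaky integrate-and-fire (LIF) neurons whose connections adapt by
spike-timing-dependent plasticity (STDP), and read out by dynamic evolving
spiking output neurons compared with K-nearest neighbours. Evaluation is
leave-one-subject-out (LOSO): every subject is classified by a model that
never saw any of their trials.

The pipeline has five stages, each exposed as package functions:

1. **Feature extraction** — `extract_facial_features()`,
   `preprocess_ecg()`, `detect_r_peaks()`,
   `extract_respiration_features()`, `extract_pupil()`,
   `assemble_feature_matrix()`. Every trial becomes a 16 x 64 matrix: each
   feature restricted to the last 30 s of the trial, resampled to 64
   samples, first sample subtracted.
2. **Spike encoding** — `fit_receptive_fields()`, `encode_trial()`. Each
   feature drives a population of five input neurons whose ranges are
   equal-count quantile bins of the pooled feature distribution; at each of
   the 64 samples exactly one neuron of the population spikes. Zeros are
   interleaved between spike opportunities, so each train is
   `2 * 64 + 1 = 129` steps long and a trial becomes an 80 x 129 raster.
3. **Reservoir** — `build_reservoir()`, `train_unsupervised()`. 847 LIF
   neurons on an 11 x 11 x 7 grid with small-world wiring, trained by one
   unsupervised STDP pass over the training rasters.
4. **Readout** — `create_output_neuron()`. One output neuron per sample,
   connected to all 847 reservoir neurons, initialised by rank-order
   coding, `w = alpha * mod^rank`, and then adjusted by a per-step drift.
5. **Classification** — `knn_classify()`, `loso_evaluate()`. Test output
   neurons are labelled by the majority of their K = 3 nearest training
   neurons in weight space.

## Neuron and plasticity models

**LIF dynamics.** Each reservoir neuron carries a post-synaptic potential
(PSP). Per synchronous step the PSP leaks by a constant 0.002 (floored at
0) and integrates the weighted spikes that arrived from neurons that fired
on the previous step. At PSP >= 0.5 the neuron fires, resets to 0 and is
refractory for one step, during which arriving spikes are ignored. Input
neurons are clamped to their encoded rasters: their own dynamics are
bypassed, which keeps the injected trains exactly deterministic.

**STDP.** When a neuron fires at `t_post`, every incoming connection whose
presynaptic neuron last fired at `t_pre` changes by

&Delta;w = sgn(&Delta;t) &middot; LR / (|&Delta;t| + 1),  &Delta;t = t_post − t_pre,

with LR = 0.001, and symmetrically every outgoing connection whose
postsynaptic neuron fired earlier is depressed. Pairing is nearest-spike
(the most recent spike on the other side). `sgn(0)` is taken as 0:
simultaneous firings leave the weight unchanged, which keeps the rule
antisymmetric. The update magnitude is bounded by LR and strictly
decreasing in |&Delta;t|; both properties are asserted in the test suite.

**Readout drift.** After a reservoir neuron's first spike initialises its
synapse onto an output neuron at `alpha * mod^rank`, the synapse gains
`drift` at every later step where the neuron fires again and loses `drift`
at every silent step. The closed form
`w = alpha * mod^rank + drift * (fires_after - silences_after)` is verified
against a per-step replay oracle in the tests. The drift clock starts at
the synapse's own first spike, not at step 0, because a synapse only
"becomes dynamic" once it exists; weights are not clipped at zero.

## Parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| grid dims | 11 x 11 x 7 | neurons | 847 neurons, spacing 10; x,y span [-50, 50], z [-30, 30] |
| small-world radius r | 25 | distance | up to two grid steps |
| connection probability | min(1, 0.15·10/d) | — | inverse distance; p0 configurable |
| excitatory fraction | 0.80 | — | enforced exactly (rounded) among recurrent edges |
| input weight multiplier | 2 | — | input-incident edges always positive |
| firing threshold | 0.5 | potential | |
| leak | 0.002 | potential/step | constant-leak model |
| refractory | 1 | step | read as one simulation step, not one second |
| STDP learning rate | 0.001 | — | |
| alpha | 1 | — | rank-order scale |
| mod | 0.8 | — | see note below |
| drift | 0.005 | /step | |
| K | 3 | neighbours | Euclidean distance on weight vectors |

Two parameter readings were genuinely ambiguous and are resolved as
package defaults with the alternative reachable through configuration:
`mod` appears both as 0.8 (methods description) and 0.84 (parameter
table); the package defaults to 0.8 and `readout_params(mod = 0.84)`
selects the other. The refractory time is printed with seconds as units,
but the simulation has no physical clock and the accompanying text speaks
of one time unit, so it is one step.

The weight initialisation draws `u/d` with `u` uniform on (0, 1] and `d`
the Euclidean pre-post distance; the 80/20 excitatory/inhibitory split is
assigned by stratified sampling rather than independent coin flips so the
printed split is an exact, testable property of every constructed network.

## Geometry of the input populations

Input populations are embedded as 16 lines of five adjacent neurons: five
facial-feature lines on the bottom grid layer (z = -30), five on the top
(z = +30), and the six peripheral lines on the middle layer (z = 0).
Within a line the five neurons (lowest range n1 to highest n5) occupy
adjacent y positions, so neurons coding similar values are spatial
neighbours and can specialise jointly. The exact x columns per layer are
deterministic functions of the grid width.

## Encoding choices

Receptive-field boundaries are midpoints between flanking order statistics
at the equal-count cut ranks, so each of the five ranges holds an equal
share of the pooled values (within one when values are distinct). Ties at
a boundary go to the lower range. A feature whose pooled values collapse
(boundaries not strictly ascending) is flagged degenerate and encodes
everything through the middle neuron n3 — a documented, deterministic
fallback rather than an error, since a constant feature carries no
information either way.

Spikes sit at odd time steps 1, 3, ..., 127 with step 0 silent, giving the
129-step trains; the silent first step lets the reservoir start from a
clean zero state before the first spikes are delivered.

Under LOSO the receptive fields are fitted on the training subjects only
by default. Pooling all subjects (as a full-cohort fit would) is available
via `eval_params(pool_all = TRUE)`; the default avoids leaking the test
subject's feature distribution into the encoder.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` draws a cohort (default 27 subjects, 14 trials each,
53.07% low valence) of 16 x 64 feature matrices. Each series is a
subject-level offset plus a slow trial drift (a Gaussian random walk
low-pass filtered below ~1 Hz at the window's 2.1 Hz sampling) plus i.i.d.
Gaussian noise (`noise_sd`, default 0.2). High-valence trials additionally
receive `effect_size` times a half-sine temporal template on the
mouth-opening (f9), mouth-width (f10) and pupil rows — the features that
carry most discriminative power in real cohorts. The half-sine makes the
effect rise and fall smoothly across the 30-s window, giving the reservoir
a temporal pattern rather than a constant offset; the class-conditional
mean difference on f10 is therefore `effect_size * mean(template)`, a
relation the tests verify by Monte Carlo.

`generate_raw_trial()` produces raw signals with ground truth for
validating the extractors: an ECG assembled from QRS-like Gaussian
templates at a stated heart rate (2% RR jitter) with respiration-locked
baseline wander, a sinusoidal respiration trace, slow temperature/GSR
drifts, a pupil series with blink gaps (`NA`) and class-dependent
dilation, and a 68-point landmark sequence whose mouth geometry widens and
opens under high valence, with the first 2 s left neutral.

What passing tests on these data do **not** show: real facial dynamics
(head pose, occlusion, expression idiosyncrasy), realistic ECG morphology
variation or arrhythmia, non-stationary breathing, subject-specific
effect directions, or class effects outside the three designated features.
Synthetic results establish that the pipeline recovers a known signal
under its own assumptions, not field performance.

## Numerical choices and degenerate inputs

* **ECG band-pass.** The 0.05–40 Hz cascade is realised as a least-squares
  linear-phase FIR low-pass (passband to 40 Hz, stopband from 45 Hz,
  ~1 s kernel) plus subtraction of a 10-s centred moving-average baseline
  (a linear-phase high-pass near 0.04 Hz). Both stages are applied
  zero-phase with reflected edges, so R-peak times are not shifted; the
  measured response at 50 Hz is below -40 dB and in-band gain is within
  the 1 dB ripple bound, asserted in tests.
* **R detection.** Pan–Tompkins stages (5–15 Hz band-pass, five-point
  derivative, squaring, 150-ms integration window, adaptive dual
  thresholds with 200-ms refractoriness and RR-gap search-back), with the
  fiducial refined to the ECG maximum within ±50 ms.
* **Sparse event series.** RR intervals and respiration cycles exist only
  at event times; they are step-interpolated (last value carried forward)
  onto the window grid before resampling, which avoids inventing
  intermediate dynamics between events. Dense series are linearly
  interpolated.
* **Flat signals.** A flat ECG or respiration trace yields an empty event
  list plus a warning, not an error; a fully missing pupil series is an
  error.
* **Ties.** First-spike ties in rank-order coding break by neuron index;
  KNN distance ties break by training order and vote ties fall back to the
  single nearest neighbour; boundary ties in encoding go to the lower
  range. All are deterministic and documented.
* **Cluster assignment.** Spike-communication clusters assign each neuron
  to the input reachable along the directed path maximising the minimum
  per-connection transmitted spike count (widest path, Dijkstra-style),
  ties broken toward the Euclidean-nearest input. Neurons with no
  positive-communication path are reported as `unassigned` rather than
  attributed to an arbitrary input, so cluster sizes still partition the
  reservoir.

## Design decisions that were genuinely open

* **Decision-level fusion** chooses, per held-out subject, between the
  facial-only and peripheral-only pipelines by their accuracy "on the
  training data". Resubstitution accuracy is near-degenerate here (each
  training sample has its own output neuron), so the package estimates it
  by an internal LOSO over the training subjects. Ties go to facial.
* **Spike placement** within the 129-step grid (leading vs trailing
  silence) is unstated in the field's descriptions; the package places
  opportunities at odd steps with step 0 silent and documents this as its
  own choice.
* **STDP during readout passes** is off: output-neuron creation propagates
  through a frozen reservoir. A switchable variant was considered and
  rejected as it makes training-order affect test encodings.
* **Trial order** during unsupervised training is the dataset order;
  `train_unsupervised(shuffle = TRUE, seed =)` provides a seeded shuffle.
* **HRV representation**: the raw RR-interval series itself (step
  interpolated), not a windowed variability statistic; temperature and
  GSR enter unfiltered.

## Evaluation protocol and problem sizes

All randomness flows from explicit seeds: the generator from
`synth_config(seed=)`, each LOSO fold's reservoir from a seed derived from
`eval_params(seed=)` and the fold index, so whole runs are reproducible
byte for byte.

The package's end-to-end validation uses a 6-subject x 12-trial synthetic
cohort with a large class effect (`effect_size = 2`, about four times the
trial noise), chosen as the smallest cohort that exercises every pipeline
stage with a fresh 847-neuron reservoir per fold while keeping a complete
run in the low minutes. On this cohort the pooled LOSO accuracy is
expected well above 80% and a label-permutation control falls to chance.
Because KNN predictions are correlated within subjects, a single
permutation draw is substantially noisier than a binomial model suggests;
the chance control therefore averages four independent label permutations
and requires the mean to sit inside the 95% binomial band around 50%.

The spike-communication cluster analysis repeats the qualitative
single-class experiment: training the reservoir on high-valence trials
alone makes the cluster around the input neuron coding the highest
mouth-width values (f10, n5) larger than when training on low-valence
trials, mirroring the feature's class effect.

## Known limitations

* The reservoir simulator is synchronous with one-step delivery on every
  connection; no per-edge conduction delays and no exponential-leak mode.
* EEG, audio and posture modalities are out of scope, as are face
  detection and landmark localisation: the pipeline consumes landmark
  coordinates, not video.
* Decision fusion's internal LOSO is quadratic in the number of subjects
  and is the slowest path in the package.
* Reported synthetic accuracies say nothing quantitative about performance
  on real cohorts; benchmark-scale results require the corresponding
  gated datasets.

## A minimal run

```{r, eval = FALSE}
trials <- generate_dataset(synth_config(n_subjects = 6,
                                        trials_per_subject = 12,
                                        class_balance = 0.5,
                                        effect_size = 2, seed = 11))
report <- loso_evaluate(trials, reservoir_params(), readout_params(),
                        eval_params(seed = 5))
report
write_report(list(feature = report), "report.csv")
```
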