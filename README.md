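# spikecube

Brain-inspired spiking-neural-network classification of binary emotional
valence (unpleasant vs pleasant) from multimodal feature time series:
facial landmark distances and peripheral physiological channels (ECG-derived
heart-rate variability, respiration variability and depth, skin
temperature, galvanic skin response, pupil diameter). The package is aimed
at affective-computing researchers who want a fully reproducible,
inspectable spiking pipeline — and a synthetic multimodal generator so that
every stage can be exercised and validated without access to
registration-gated affect databases.

## The method

Each trial is reduced to a 16 × 64 feature matrix (last 30 s of the trial,
resampled to 64 samples, first sample subtracted) and then classified in
four spiking stages:

1. **Population spike encoding.** Every feature drives five input neurons
   whose receptive fields are equal-count quantile ranges of the pooled
   feature distribution; at each sample exactly one neuron of the
   population spikes. With zeros interleaved, each train is
   2·64 + 1 = 129 steps, and a trial becomes an 80 × 129 spike raster.
2. **3D LIF reservoir.** 847 leaky integrate-and-fire neurons on an
   11 × 11 × 7 grid (spacing 10) with small-world wiring inside radius
   r = 25: connection probability min(1, p₀·10/d), weight u/d with u
   uniform on (0, 1], exactly 80% excitatory among recurrent edges,
   input-incident edges positive with doubled weight. PSP dynamics:
   constant leak 0.002/step, threshold 0.5, reset to 0, one refractory
   step.
3. **Unsupervised STDP.** One pass over the training rasters with
   nearest-spike pairing and

   Δw = sgn(Δt) · LR / (|Δt| + 1),  Δt = t_post − t_pre,  LR = 0.001.

4. **deSNN readout + KNN.** One output neuron per sample over the frozen
   reservoir, initialised by rank order, w = α·mod^order (α = 1,
   mod = 0.8), then drifted ±0.005 per step after each synapse's first
   spike. Test neurons are classified by their K = 3 nearest training
   neurons (Euclidean distance on weight vectors).

Evaluation is leave-one-subject-out (LOSO) with feature-level fusion (all
16 features in one reservoir), decision-level fusion (per held-out subject,
the better of the facial-only and peripheral-only pipelines as estimated on
the training subjects), or either single modality. Reports follow the
per-subject accuracy/F1 table layout with a pooled `Total` row.

## Worked example

```r
library(spikecube)

trials <- generate_dataset(synth_config(n_subjects = 6,
                                        trials_per_subject = 12,
                                        class_balance = 0.5,
                                        effect_size = 2, seed = 11))
report <- loso_evaluate(trials, reservoir_params(), readout_params(),
                        eval_params(seed = 5))
report
```

```
<eval_report> fusion mode: feature
 subject  n  accuracy        f1
     S01 12 100.00000 1.0000000
     S02 12  83.33333 0.6666667
     S03 12  75.00000 0.7692308
     S04 12  91.66667 0.8888889
     S05 12  83.33333 0.8000000
     S06 12  83.33333 0.8333333
Total: accuracy 86.11%, F1 0.844 (72 trials)
```

The synthetic cohort plants an additive class effect (here twice the
feature scale, shaped by a half-sine over the window) on the mouth-opening,
mouth-width and pupil features of high-valence trials. Each of the six LOSO
folds builds and STDP-trains a fresh 847-neuron reservoir on the other five
subjects and classifies the held-out subject's twelve trials; the pooled
accuracy of 86.11% (F1 0.844 for the high-valence class) shows the
reservoir-plus-readout recovering a signal it was never shown for that
subject. With `effect_size = 0` the same pipeline is at chance.

Raw-signal users start one stage earlier:

```r
cfg <- synth_config(n_subjects = 2, trials_per_subject = 2,
                    trial_duration = 60, seed = 3)
raw <- generate_raw_trial("high", cfg, seed = 42, heart_rate_bpm = 60)
trial <- extract_trial_features(raw)       # 16 x 64 labelled matrix
```

`detect_r_peaks()` (Pan–Tompkins) recovers the generator's ground-truth RR
intervals to ~1 ms mean absolute error on such data, and the respiration
cycle extractor returns the exact 4-s period and 2·A depth of a sinusoidal
trace; both tolerances are asserted in the test suite.

A command-line interface wrapping these stages (subcommands `simulate`,
`extract`, `encode`, `train`, `loso`, `clusters`) is installed at
`inst/cli/spikecube.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/spikecube.R", package="spikecube"))')" \
  simulate --n-subjects 6 --trials-per-subject 12 --effect-size 2 \
  --seed 11 --out features.csv
```

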