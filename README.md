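# ssvepbci

Simulation and analysis of SSVEP brain-computer-interface studies with a
neuromodulation arm.

Steady-state visual evoked potentials (SSVEPs) are EEG responses locked to
the frequency of a flickering target; SSVEP BCIs identify the attended
target by matching occipital EEG against harmonic references. Studies of
excitatory rTMS over visual cortex ask whether stimulation improves decoding
and, mechanistically, whether any gain comes from amplifying the
stimulus-locked response or from suppressing occipital background activity.
Because such human datasets are rarely shared, this package pairs the
complete analysis chain with a synthetic 64-channel EEG generator in which
the mechanism is planted with known ground truth, so every estimator is
validated end-to-end.

It is intended for BCI/EEG methods researchers who need a tested,
reproducible reference implementation of this analysis stack, and for
simulation studies of the suppression mechanism itself.

## What is implemented

* **Synthetic data** — harmonic SSVEP trials over an occipital topography
  with 1/f^χ background and alpha rhythm; full multi-band sessions
  (LF/MF/HF/SHF × five 1 Hz-spaced targets × four blocks); resting
  recordings; semi-Markov microstate EEG (classes A-D); rTMS pulse-schedule
  arithmetic. Condition/timepoint effect gains (background suppression κ,
  alpha gain, microstate-B occurrence gain) are the ground truth every
  estimator is checked against.
* **I/O & preprocessing** — BrainVision triplet read/write, zero-phase 1-90 Hz
  Butterworth bandpass with anti-aliased resampling (5 kHz → 250 Hz),
  epoch extraction, plain-text trial-set persistence.
* **Decoders** — filter-bank canonical correlation analysis (FBCCA) with
  sub-band weights w(n) = n^-1.25 + 0.25, and task-discriminant component
  analysis (TDCA) with delay augmentation, reference projection and
  leave-one-block-out evaluation.
* **Evaluation** — accuracy-versus-duration curves (0.5-4 s) reduced to the
  cumulative decoding effect, CDE = area under the curve / total area
  (equivalently the mean of the eight accuracies), range 0-100%.
* **Spectral** — Parseval-consistent periodograms; task-related power (the
  bin at the stimulation frequency) vs task-unrelated power (mean within
  ±1 Hz excluding that bin); narrow and wide (harmonic-sum) SNR in dB; Welch
  band power; CCA similarity scores for fundamental and second harmonic.
* **Microstates** — polarity-invariant modified k-means on GFP-peak
  topographies (k = 4, restarts, GEV selection, canonical A-D naming),
  backfitting, duration/occurrence/contribution metrics, transition
  matrices.
* **Statistics** — channel-space cluster-based permutation test (paired t,
  scalp adjacency, max-cluster-mass Monte-Carlo null under sign flips),
  Benjamini-Hochberg FDR, paired t / Pearson r, and a thin `lmerTest`
  adapter for the mixed-model stage.
* **Pipeline** — `run_pipeline(study_config())` simulates the full
  sham-controlled within-subject study (Pre/Post0/Post20 × real/sham) and
  writes TSV/JSON report tables, byte-reproducible from one master seed.

## Worked example

```r
library(ssvepbci)

spec <- session_spec(bands = list(MF = c(18, 22)))
sham <- generate_session(spec, signal_model(), effect_config(), seed = 42)
real <- generate_session(spec, signal_model(),
                         effect_config("real", "Post0", background_gain = 0.6),
                         seed = 42)

cfg <- fbcca_config(band_lo = 18)
dec <- fbcca_decoder(band_targets(spec, "MF"), cfg, fs = 250)
curve_sham <- accuracy_curve(dec, sham)
curve_real <- accuracy_curve(dec, real)
round(curve_sham$accuracy, 1)
#> [1]  55  95  95 100 100 100 100 100
round(curve_real$accuracy, 1)
#> [1]  75  95 100 100 100 100 100 100
sprintf("CDE sham: %.2f%%  real: %.2f%%",
        compute_cde(curve_sham), compute_cde(curve_real))
#> "CDE sham: 93.12%  real: 96.25%"
```

The two sessions share every seed, so they differ only in the planted
mechanism: occipital background power is multiplied by κ = 0.6 in the
"real" session. Decoding accuracy at short durations rises (55% → 75% at
0.5 s), the CDE summary rises by ~3 points, and the mean narrow-band SNR
across the 20 trials rises from 20.7 dB to 22.9 dB while the task-related
power itself is unchanged — the suppression mechanism, recovered by the
analysis.

Protocol arithmetic is available directly:

```r
s <- generate_rtms_schedule(n_trains = 24, train_duration = 10,
                            pulse_rate = 5, inter_train_interval = 5)
c(s$n_pulses, s$duration / 60)
#> [1] 1200    6
```

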