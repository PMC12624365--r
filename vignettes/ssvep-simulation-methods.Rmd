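---
title: "Simulating and analysing SSVEP-BCI neuromodulation studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing SSVEP-BCI neuromodulation studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepbci)
```

## The problem this package addresses

Steady-state visual evoked potentials (SSVEPs) are periodic EEG responses at
the frequency of a flickering visual target and its harmonics. SSVEP-based
brain-computer interfaces (BCIs) identify which of several targets a user is
attending by matching occipital EEG against harmonic reference signals.
A central question in neuromodulation research is whether excitatory rTMS
over primary visual cortex improves SSVEP decodability — and, mechanistically,
*how*: by amplifying the stimulus-locked (task-related) response, or by
suppressing the occipital background activity (task-unrelated power) against
which that response must be detected.

Human datasets for such studies are rarely public. This package therefore
pairs the complete analysis chain (decoders, spectral decomposition,
microstate dynamics, cluster statistics) with a synthetic EEG generator in
which the mechanism is *planted* with known ground truth, so every estimator
can be validated end-to-end: if the generator suppresses occipital background
power by a factor $\kappa < 1$, the analysis must recover higher SNR,
unchanged task-related power, and better decoding — and nothing else.

## The generative model

A trial at stimulation frequency $f$ on channel $c$ is

$$x_c(t) = w_c \sum_{h=1}^{H} a_1 r^{h-1} \sin(2\pi h f t + h\phi)
  + g_c\,\sigma\,\eta_c(t) + \sqrt{\alpha_g}\, a_\alpha w_c \sin(2\pi f_\alpha t + \varphi),$$

with:

* $w_c$ — occipital topography: a Gaussian in scalp distance from Oz
  ($\sigma_{\text{topo}}$ = 5 cm, maximum normalized to 1) over the standard
  64-channel 10-20/10-5 template coordinates. A real forward model is
  deliberately out of scope; any fixed monotone occipital weighting serves
  the validation purpose.
* $a_1$ — fundamental amplitude (default 1.5 µV), $r$ — geometric harmonic
  decay (default 0.5), $H$ — harmonics (default 2, which keeps every target
  of the 38-42 Hz band below the 125 Hz Nyquist limit at 250 Hz).
* $\eta_c$ — independent $1/f^{\chi}$ background per channel ($\chi = 1$),
  synthesized by spectrally shaping white Gaussian noise, scaled to RMS
  $\sigma$ (default 5 µV). The default was chosen once so that the
  filter-bank CCA accuracy-versus-duration curve looks like typical
  published SSVEP curves (roughly 60% correct at 0.5 s, >90% at 1 s,
  ceiling at 4 s for five targets); it was not tuned against any test.
* $g_c = \sqrt{\kappa}$ on the nine occipito-parietal channels and 1
  elsewhere — the planted neuromodulation mechanism. `background_gain`
  $\kappa$, `alpha_gain` $\alpha_g$ and the microstate-B occurrence gain are
  all 1 under sham stimulation and at the pre-stimulation timepoint by
  construction.
* the alpha rhythm (10 Hz, 2 µV, random phase) overlaps the 8-12 Hz
  stimulation band, reproducing the realistic confound that low-frequency
  SSVEP targets compete with endogenous alpha.

Sessions follow the four-band layout (LF 8-12, MF 18-22, HF 28-32,
SHF 38-42 Hz; five 1 Hz-spaced targets; four blocks; 0.5 s cue / 4 s
flicker / 0.5 s rest), with band order and target order randomized per block
under a derived seed. Stimulus phases follow the sampled-phase convention
$0.35\pi(k-1)$. The generator runs natively at 250 Hz; a 5 kHz mode exists
only to exercise the bandpass-and-resample path (1-90 Hz zero-phase
4th-order Butterworth cascade, polyphase resampling).

The rTMS protocol itself is represented only as pulse-schedule arithmetic
(`generate_rtms_schedule()`); by the package's schedule convention the
trailing inter-train interval counts toward the protocol duration, so
24 trains × (10 s + 5 s) = 6 min carry 1200 pulses.

### Microstate-structured EEG

Resting/task microstate dynamics are generated by a semi-Markov chain over
four canonical map topographies (A/B: the two diagonal occipito-frontal
gradients; C: anterior-posterior; D: fronto-central focal — documented
analytic templates, average-referenced and unit-norm). Dwell times are
gamma-distributed (shape 2, mean 80 ms); jumps follow a row-stochastic
transition matrix with zero diagonal. The active map is rendered through an
oscillatory global-field-power envelope (10.3 Hz, floor at 40% of its 5 µV
scale so no sample is silent) scaled such that the clean-signal GFP equals
the envelope, plus white sensor noise (1 µV, i.e. 20-25% of the envelope).
The `microstateB_occurrence_gain` multiplies the transition probability
*into* class B and renormalizes rows: B segments become more frequent while
dwell distributions are untouched.

## The estimators

**FBCCA** decomposes a trial into $N$ sub-bands (band-dependent defaults
7/5/3/2 for LF/MF/HF/SHF), computes the first canonical correlation
$\rho_{k,n}$ between each sub-band and the harmonic sine-cosine reference of
each candidate $f_k$, and scores
$\bar\rho_k = \sum_n (n^{-1.25} + 0.25)\,\rho_{k,n}^2$; the prediction is the
arg-max with ties broken toward the lowest frequency. Sub-band $n$ spans
$[n f_{\text{lo}}, 95]$ Hz; references use $\min(5, \lfloor 95/f \rfloor)$
harmonics so they stay inside the analysis band, and any harmonic at or above
Nyquist is dropped with a warning, never aliased. The CCA core is a QR/SVD
of column-centered matrices (pivoted QR guards rank deficiency).

**TDCA** is the calibration-based decoder: each trial is delay-augmented
($\ell = 3$ shifted copies) and concatenated with its projection onto the
class's sine-cosine subspace; discriminant filters solve the generalized
eigenproblem of between- versus within-class scatter (ridge $10^{-6}$ of the
mean diagonal, with an explicit warning when the scatter is near-singular),
and classification correlates the filtered trial with class templates.
**We default to 2 spatial filters, not the 8 sometimes used with large
montages**: with leave-one-block-out calibration the model sees only three
trials per class on a 9-channel montage, and a sweep showed 8 components
overfitting badly (≈50-80% vs ≈90-100% accuracy at 1 s). Both $\ell$ and the
component count remain arguments.

**CDE.** Decoding accuracy is evaluated on the leading 0.5, 1.0, ..., 4.0 s
of each trial, and the curve is reduced to the cumulative decoding effect:
the ratio of the area under the accuracy-versus-duration curve to the total
attainable area, range 0-100%. With equal-width duration bins and a
rectangle rule this is exactly the mean of the eight accuracies, which is
the default realization; trapezoidal quadrature is available behind a flag
since the quadrature is a convention, not a result.

**Spectral decomposition.** Task-related power is the periodogram bin at the
stimulation frequency of the channel-averaged occipital montage (4-s
single-taper periodogram, 0.25 Hz resolution, Parseval-consistent);
task-unrelated power is the mean over bins within ±1 Hz excluding that bin;
their ratio in dB is the narrow-band SNR (dB chosen so condition effects add).
The wide-band SNR has no canonical definition; this package realizes it as
$10\log_{10}\left(\sum_h P(hf) \,/\, \sum_h \bar P_{\text{bg}}(hf)\right)$
over the usable harmonics, which reduces exactly to the narrow-band SNR at
$N_h = 1$ and is 0 dB for a flat spectrum. This choice is flagged for
sensitivity analysis. Resting band power uses Welch averaging (2-s Hann
segments, 50% overlap). Similarity scores are first canonical correlations
between the multichannel trial and the sine-cosine pair at $f$ (or $2f$).

**Microstates.** Polarity-invariant modified k-means on the topographies at
GFP peaks of average-referenced data (squared-projection assignment; map
update = principal eigenvector of the assigned outer-product sum), best of
`n_restarts` seeded restarts by global explained variance. Fitted maps are
named A-D by maximizing total absolute spatial correlation to the canonical
templates over all label permutations, so "microstate B" is comparable
across runs. Backfitting labels every sample by maximal absolute spatial
correlation; a minimum-duration smoothing rule exists but is off by default
(whether the original analyses smoothed is unknown, so the default is the
weaker assumption). Mean duration excludes runs truncated at the recording
edges (they are censored observations) unless a class occurs *only* in edge
runs; occurrence and contribution count all runs. Transitions are counted at
run boundaries only. Note the restart budget matters: with few restarts the
fit occasionally lands in a lower-GEV optimum that splits the most frequent
class into two maps; 10+ restarts resolved this in every seed we probed, and
the global optimum is clearly separated by GEV.

**Cluster-based permutation test.** Paired per-channel t-values are
thresholded at the critical t for $\alpha = 0.05$; supra-threshold channels
are clustered by template-coordinate adjacency (≤ 4 cm default — the
conventional sensor-level criterion; configurable since no canonical value
exists); cluster mass is the summed t; the Monte-Carlo null is the maximum
cluster mass under within-subject sign flips (batched as a single
flip-matrix product, since squared differences are flip-invariant), with
plus-one-corrected p-values. FDR control is Benjamini-Hochberg (the
procedure choice when only "FDR" is specified). The rm-ANOVA/LMM stage is
deliberately delegated to `lmerTest` behind the thin adapter
`fit_effect_lmm()` — mixed-model internals are not this package's
contribution.

## The pipeline and its study conditions

`run_pipeline(study_config())` simulates the full sham-controlled
within-subject study: subjects get log-normal multipliers (sdlog 0.2) on
signal and noise scales so mixed-model stages see genuine between-subject
variance, plus a phosphene-threshold covariate (PT, 60 ± 8% stimulator
output) that scales effect gains linearly — lower PT (higher cortical
excitability), stronger planted effect. No physiological model is claimed
for this coupling; it exists so the correlation stages have recoverable
structure. Default planted effects: real-Post0 $\kappa = 0.6$, alpha gain
1.4, B-occurrence gain 1.4; real-Post20 halves the deviations from 1 (a
partially decayed after-effect); sham and Pre are exact nulls. Every stage
writes a TSV keyed by a hash of the stage configuration and is skipped when
its file already exists; all randomness derives from one master seed, so
reruns are byte-identical.

## What the tests do and do not show

The suite validates *estimator correctness* (exact brute-force oracles for
CDE, GEV, cluster mass, FDR; analytic SNR of a sinusoid in white noise
within 1 dB; map/dwell/transition recovery within 5-10%), *statistical
calibration* (cluster-test family-wise error inside the 95% binomial CI of
0.05 over 500 null simulations with 24 subjects × 64 channels), and
*mechanism recapitulation* (halving occipital background power raises
per-trial SNR and decoding margin with task-related power unchanged in
aggregate; raising the B-occurrence gain raises estimated B occurrence and
contribution). Problem sizes were chosen as the smallest that leave the
assertions comfortable margins: 120-600 s of microstate data, 80-trial
sessions, 500 × 500 permutation null.

Passing these tests shows the chain is correct *for data of this structure*.
The generator deliberately omits ocular and muscle artifacts (the artifact
stage is a pass-through hook), volume-conducted correlated noise, electrode
drift, non-stationarity of the background, and any real head model — so the
suite cannot certify performance on human EEG, only that each estimator
measures what it claims to measure when the truth is known.

## Numerical conventions and degenerate inputs

Samples are 0-based and epochs half-open $[t_0, t_1)$; BrainVision INT_16
payloads use 0.1 µV resolution (≤ 0.05 µV round-trip error). FBCCA ties
break toward the lowest candidate; identical paired samples return $t = 0$,
one-tailed $p = 0.5$; a constant nonzero paired difference is an error for
`paired_t()` but maps to an infinite channel t in the permutation test's
vectorized path; zero-variance maps are rejected by `spatial_correlation()`.
Single-trial task-related power carries a signal × background cross term of
a few percent — invariance claims about it are exact for the stimulus-locked
component (same-seed difference test) and hold within 1% only in aggregate.
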