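---
title: "lungrx: models, design choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lungrx: models, design choices, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lungrx` couples an audio-based eight-class respiratory diagnoser with a
synthetic-data prescription recommender. This vignette is the package's own
account of the science: the models, their assumptions, the parameters that
matter, the places where the design was genuinely open and what we chose,
and what passing tests do and do not establish.

## 1. The feature pipeline

Clips are loaded mono at 22,050 Hz (multichannel input is average-downmixed
before polyphase resampling). Features are mel-frequency cepstral
coefficients: centered STFT (Hann window, 2048-sample window, 512-sample
hop — standard analysis settings chosen once and documented so the
frame-count arithmetic `1 + floor(n/hop)` is independently checkable), power
spectrum, 64 triangular HTK-mel filters, log compression, orthonormal
DCT-II, first 52 coefficients. Every matrix is then length-normalized to
926 frames: shorter clips are right-padded with zero columns, longer clips
keep their first 926 frames. Truncation keeps the onset because it is
deterministic and preserves temporal order; 926 frames at hop 512
corresponds to about 21.5 s of audio, so typical 10–90 s recordings are
either zero-padded or onset-truncated post-featurization.

Label encoding is a fixed bijection over the eight class names in
case-insensitive lexicographic order; a fitted encoder's order would be an
invisible state dependency, so the order is a constant.

An optional per-coefficient z-score scaler (`fit_mfcc_scaler`) exists but is
off in the canonical pipeline, which only length-normalizes. The scaler is
fit on training clips only and removes the large dynamic-range disparity
between low- and high-order cepstra; the reduced-scale training protocol
(Section 6) uses it because small-batch optimization is visibly slowed
without it.

## 2. The synthetic sound generator

Real auscultation data cannot ship with a package, so the `fixtures` module
synthesizes class-conditional clips with the statistical structure the
architecture exploits: wheezes are slowly frequency-wandering tones confined
to a class-specific band and to a fraction of the clip (horizontal
spectrogram ridges); crackles are exponentially damped broadband clicks at a
class-specific rate (vertical spikes); breath noise is amplitude-modulated
broadband noise at ~0.25 Hz. The class-to-recipe table gives each class a
distinct but partially overlapping parameterization (COPD and LRTI share
neighbouring low-frequency wheeze bands, mimicking their clinical
confusion). Default clip duration is 10 s — the lower end of realistic
recording lengths; tests use shorter clips since the acoustic cues are
stationary in duration.

What the fixtures do *not* emulate: heart sounds and other body-noise
confounders, device transfer functions, chest-location effects,
inter-subject anatomical variability (subjects differ only through random
draws of the same recipe), and the non-stationarity of real breath cycles.
Consequently, a high held-out accuracy on fixtures shows the pipeline can
learn separable spectro-temporal structure under leakage-safe protocols —
it says nothing about clinical performance on real patients.

## 3. Augmentation with a fidelity gate

Class balancing is three-staged: extreme minorities (LRTI, asthma,
bronchiolitis) pass a 25x up-sampling stage first; all deficient classes are
then iteratively topped up to a per-class target drawn uniformly on
[720, 760] per run (classes already above 760 are untouched). Candidates
mix classical waveform transforms (pitch shift within ±2 semitones, phase-
vocoder time stretch 0.8–1.2x, gain within ±6 dB, noise injection at
5–30 dB SNR, white or pink) with a deterministic parametric surrogate
generator — a convex time-domain mixture (weight 0.3–0.7) of two same-class
clips followed by one classical transform — filling the 40% "generative"
quota. The surrogate replaces a learned generator deliberately: at desk
scale the operative safeguard is the *validation gate*, not the generator.

The gate accepts a candidate iff the peak normalized cross-correlation
between smoothed mel-band log-spectrograms of source and candidate exceeds
r = 0.85. Design of the statistic: 32 mel bands over 50–2500 Hz (where
adventitious sounds live), an 80→60 dB floored log scale, boxcar smoothing
over ~0.25 s and 3 bands, Pearson correlation maximized over ±6 frame and
±2 band lags. Smoothing makes the statistic compare the slow
spectro-temporal envelope (breath cycles, wheeze ridges, crackle showers)
rather than stochastic fine texture; the band-lag search absorbs legitimate
in-range pitch shifts. Under this statistic, in-range transforms score
0.86–0.99 and cross-class or tone-versus-noise pairs score below 0.5, so the
0.85 threshold separates cleanly. Rejected candidates are regenerated up to
a retry budget (default 8 per needed clip); exhausting it is an error naming
the class.

Every retained clip inherits its source clip's subject id, which is what
makes the leakage audit (Section 7) possible by construction.

## 4. The hybrid diagnoser

Architecture (variant `"full"`): Input (926 x 52) → Conv1D(64, k5, same,
ReLU) → BatchNorm → Conv1D(128, k3, same, ReLU) → BatchNorm → MaxPool(2) →
LSTM(128, sequences) → attention → LSTM(64, final state) → Dropout(0.5) →
Dense(128, ReLU) → Dense(8, softmax). Two batch-norm layers are used, one
after each convolution. An optional second ReLU dense layer is available
behind a config flag but off by default. Attention scores each step through
64 tanh units and a linear read-out; the weights are a softmax over time.

Numerical and design choices worth knowing:

- **Attention-weighted sequence, rescaled.** The second LSTM consumes the
  weighted sequence `{alpha_t * h_t}`, preserving both the "weighted sum"
  and the "final hidden state" readings of the design. Because softmax
  weights sum to 1, the raw weighted sequence has scale 1/T, which starves
  the downstream recurrence; we therefore rescale by T so uniform attention
  is the identity and softmax weighting redistributes mass instead of
  shrinking it. Without this, training stalls near chance for many epochs.
- **Gate order and initialization.** LSTM weights are fused in
  forget/input/candidate/output block order, Glorot-uniform, with the
  forget-gate bias at 1 (the standard remedy for early forgetting).
- **Batch normalization** uses biased batch statistics in training and
  running statistics (momentum 0.99) in evaluation. After early stopping
  restores the best weights, the running statistics are *recalibrated* as
  population statistics of the training set under those weights — with few
  epochs the exponential running average is still dominated by its
  initialization, and evaluation-mode normalization would otherwise be
  miscalibrated.
- **Optimization.** Adam (lr 0.001, beta1 0.9, beta2 0.999), L2 weight decay
  0.001 on weight matrices (not biases or batch-norm affine parameters),
  global gradient-norm clipping at 5 (the usual stabilizer for recurrent
  nets; without it, small-batch runs occasionally diverge), categorical
  cross-entropy, shuffled mini-batches of 32, stratified 0.2 validation
  split, early stopping with patience 10 under a strict-improvement rule,
  best-weight restoration. One integer seed controls initialization,
  shuffling, the split, and dropout masks; stratification iterates classes
  in first-appearance order so results do not depend on the collation
  locale.
- **Ties in max pooling** keep the earlier frame (deterministic).
- **Variants** for ablation: `no_attention` replaces attention with uniform
  weighting (the identity under the rescaled convention) and `cnn_only`
  removes both LSTMs, global-average-pooling the conv features into the
  dense head. A joint diagnosis+prescription head and a transformer encoder
  are documented relatives but are not implemented: they require paired
  audio-prescription data this artifact does not contain.

Every layer's backward pass is checked against central-difference numerical
gradients (relative error ~1e-6 at eps 1e-4) for all three variants, and
forward passes against independent brute-force transcriptions.

## 5. Simulated biomarker fusion

Twenty distinct markers cover the eight classes (three per non-healthy
class; IL-6 shared by pneumonia and COPD; healthy is baseline-only). The
literature motivates which markers associate with which disease but not the
magnitudes, so all listed associations get one elevation weight (0.8) over
a 0.1 baseline, both overridable via the YAML knowledge file. A sample's
molecular vector is `baseline + sum_d posterior_d * weight_{d,m}` plus
Gaussian noise, clipped to [0, 1]. The posterior driving the simulation is
the *audio model's prediction*, at training and at inference — driving it
with true labels would leak the answer into the fused channel, so that mode
exists only as an explicit option. Fusion happens at the penultimate layer:
a softmax head over `[latent, molecular]`. Because the molecular vector is
a function of the audio posterior, fusion at best refines calibration on
fixtures; the directional test (fused >= audio-only) is therefore the
honest claim, not a gain magnitude.

## 6. The prescription half

The cohort generator is an explicit rule engine, which makes every safety
property testable:

- **Demographics.** Diagnoses are drawn from a respiratory-burden-weighted
  prevalence vector (COPD .30, asthma .20, URTI .15, pneumonia .12, healthy
  .10, bronchiolitis .06, bronchiectasis .04, LRTI .03 — chosen once so
  every formulary drug has non-zero support at n = 2000, and overridable).
  Ages are diagnosis-appropriate (bronchiolitis 1–4, COPD 40–90, others
  broad); smoking applies from age 15 at 25%; anticoagulant co-medication is
  age-graded (10% at 65+).
- **Comorbidity quota.** Exactly `round(0.15 n)` records carry renal and/or
  hepatic impairment — quota sampling, not Bernoulli, so the 15% share is an
  exact contract. eGFR is Uniform(15, 59) when renal-impaired and
  Normal(95, 15) truncated at 60 otherwise, making `renal_impaired ==
  (eGFR < 60)` true by construction.
- **Prescription rules.** The formulary maps (diagnosis, age band, smoking)
  to a (drug, dosage, frequency) triple whose codomain is exactly the
  10/14/10-class output vocabularies; contraindication filters ban
  beta-blockers in asthma, NSAIDs under renal impairment, and tetracyclines
  under age 12, each with a defined alternate; a 25-pair anticoagulant-
  centred interaction table reroutes interacting first-line drugs; renally
  cleared antibiotics get `base * min(1, eGFR/60)` snapped to the nearest
  plain-mg dosage class, ties to the lower (conservative) class. Range-style
  dosage labels ("0.63-1.25 mg", "400-600 mg") are opaque class names.
- **Oversampling.** Diagnosis-drug pairs below 5% prevalence are lifted to
  the threshold by mixed-type synthetic interpolation (numeric features
  interpolated between same-pair neighbours, categoricals and targets copied
  from the nearer neighbour; single-row pairs duplicate with age jitter) —
  strictly inside the training partition, after the 80/20 split, to avoid
  synthetic leakage into evaluation.
- **Recommender.** One 500-tree probability forest (Gini, depth 15, min
  leaf 2) over the joint `drug | dosage | frequency` label, decoded into the
  three targets: a single ensemble jointly predicting all outputs. Features
  are one-hot categoricals plus standardized age and raw eGFR/weight.
  Low-confidence predictions (joint posterior < 0.5) are flagged for
  review.

Because labels are a deterministic function of features (label noise is a
switch, default 0), held-out accuracy approaches 1 by design. The ~0.99
accuracies and macro F1 scores the tests and acceptance script compute are
a property of this synthetic construction and say nothing about prescribing
quality on real patients.

## 7. Evaluation protocols

All protocols are subject-grouped, and every training partition is audited
against the held-out subjects *including augmented derivatives* (each
augmented clip carries its source subject). A violation is a hard error,
never a warning — an injected-fault test asserts the abort. LOSO retrains
from scratch each fold; grouped stratified k-fold deals subjects to folds
round-robin within class; the SNR sweep corrupts clean held-out clips at
5/10/15/20 dB with fresh seeds and re-featurizes. Proportion intervals use
the Wilson score (well-behaved near 0 and 1, where these accuracies live);
kappa uses the standard chance-corrected form with a percentile bootstrap
CI, and is checked against exhaustive enumeration and an independent
implementation. Per-class AUC is one-vs-rest; macro AUC is the unweighted
mean.

## 8. Explainability

Attention traces are the forward-pass alpha weights over the pooled time
axis; on sparse-crackle fixtures the top-decile attention mass overlaps the
known burst windows. For the recommender, the default global attribution is
permutation importance (label-flip rate of the predicted drug under
column permutation — assumption-light and cheap); exact Shapley values via
full coalition enumeration (absent features marginalized over a background
sample) provide local, signed attributions whose sum satisfies the
additivity identity by construction. Diagnosis dominates both rankings on
the default cohort, as the generating rules dictate.

## 9. Problem sizes used by the tests and the acceptance script

Pure-R training is compute-bound, so the automated checks use a reduced
protocol chosen once: a balanced fixture of 25 clips x 5 subjects per class
(3 s clips), 26 MFCCs over 128 frames with the training-set scaler, and a
proportionally narrowed architecture (conv 24/48, LSTM 48/24, attention 24,
dense 48) trained 15 epochs with batch 8, lr 0.005, dropout 0.2. Under this
protocol held-out-subject accuracy exceeds 0.9 across seeds. The
acceptance script runs the prescription experiment at full scale (n = 2000,
ten seeds) and the augmentation balancing run on the full 920-clip
imbalanced fixture with 2 s clips — the balancing targets and retained
counts do not depend on clip duration.

## 10. Known limitations

- The fixture generator's class signal is carried almost entirely by
  stationary spectral statistics. One measured consequence: the CNN-only
  ablation variant, which global-averages conv features, matches or exceeds
  the full recurrent model on fixtures at reduced scale — the opposite of
  the direction expected on real auscultation data, where wheeze duration
  and crackle timing carry diagnostic load. The ablation harness reports
  whatever it measures; on synthetic fixtures the recurrent half mainly adds
  optimization burden.
- Biomarker vectors are simulations driven by the audio posterior; fusion
  results are calibration-level statements only.
- The prescription engine is a proof of concept over synthetic labels;
  rare multimorbidity (simultaneous renal + hepatic logic beyond dose
  capping) and interactions beyond the 25-pair table are not modelled.
- The WAV reader covers PCM and IEEE-float RIFF containers; compressed
  formats are out of scope.
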