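---
title: "Beat-to-beat cross-modal fusion of ECG and PCG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beat-to-beat cross-modal fusion of ECG and PCG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Synchronized electrocardiogram (ECG) and phonocardiogram (PCG) recordings
capture complementary views of the same cardiac cycle: the electrical
activation sequence (P wave, QRS complex, T wave) and its mechanical
consequences (the S1 and S2 heart sounds, plus murmurs when flow is
turbulent). `cardiofuse` implements an end-to-end pipeline for binary
normal/abnormal classification of such paired recordings: beat-to-beat
segmentation on S1-to-S1 intervals, fixed-length resampling, a
three-branch 1-D convolutional network with progressive attention-based
cross-modal fusion, class-weighted training, cross-validated evaluation,
and a missing-modality protocol.

## Preprocessing

Each record is z-score normalized per channel over the whole record
(normalization precedes segmentation, so relative amplitude changes between
beats survive). Using supplied S1 onset annotations, consecutive onsets
$(s_i, s_{i+1})$ delimit one cardiac cycle; the half-open slice
$[s_i, s_{i+1})$ is cut from *both* channels — always the same sample range,
preserving synchronization — and linearly resampled to 2000 samples (1 s at
2000 Hz). Slices shorter than 0.1 s or longer than 3 s are treated as
annotation glitches: skipped and logged, never fatal. A record with $K$
usable onsets yields $K - 1$ segments.

Cross-validation folds are assigned at the segment level by stratified
random partition. Subject identity is not available in the target data
regime, so segment-level splitting matches the evaluation the method is
normally reported with; a record-level grouping mode is available for
stricter leakage control (`make_folds(..., group_by_record = TRUE)`).

## The network

Both modalities pass through architecturally identical but
weight-independent encoders of four levels. Each level is one
convolution–batch-norm–ReLU (CBR) block followed by two residual blocks;
each residual block embeds a squeeze-and-excitation (SE) gate
$\tilde X = X \odot \sigma(W_2\,\delta(W_1\,\mathrm{GAP}(X)))$ that
reweights channels by their pooled global statistics. All kernels are
size 7. The level's stride-5 downsampling is applied once, in the CBR
convolution; the residual convolutions are stride 1. For a 2000-sample
input the level outputs are $(2000, 64)$, $(400, 128)$, $(80, 192)$ and
$(16, 256)$ (length, channels). At levels 3 and 4 the raw input signal,
average-pooled with windows 5 and 25 so its length matches the level
*input* (400 and 80), is added to the incoming feature map, broadcast
across channels — a parameter-free skip that refreshes the morphological
signal at depth. The pooling windows only make sense at the level inputs;
this fixes the one ambiguity in the level arithmetic and is asserted by the
shape tests.

The fusion branch runs one selective attention module per level,
sequentially from shallow to deep. At level $l$, the ECG and PCG feature
maps are concatenated ($2C_l$ channels) and pass a spatial-attention stack:
a 1×1 convolution reducing channels to $\max(2C_l/4, 8)$, a ReLU, a
kernel-16 convolution (even kernel; padded asymmetrically, 8 left / 7
right), a ReLU, then a 1×1 convolution to exactly 2 channels and a sigmoid
— producing one weight map per modality. Each map multiplies its own
modality's features position-wise, and the two weighted maps are
re-concatenated into $V_s$. Channel attention then mirrors the SE recipe on
$V_s$ (GAP, bottleneck ratio 16, sigmoid) and rescales it per channel.
Finally the previous level's fused output, average-pooled by 5 to the
current length, is concatenated with the attended features and merged by a
batch-norm → kernel-7 convolution → ReLU to $C_l$ channels (level 1 has no
history and merges the attended features alone). With all attention weights
zero every gate is exactly $\sigma(0) = 0.5$ — a closed-form anchor the
tests assert.

The classification head applies a kernel-3 stride-2 convolution (16 → 8
positions), global average pooling, then dense layers 128 → 64 → 32 → 2
with ReLU and dropout 0.5 after each hidden layer, and a softmax. The
positive class is "abnormal"; confusion metrics threshold the abnormal
probability at 0.5.

Nine variants share this vocabulary (`cf_variants()`): the full model;
single-modality branches (one encoder + head); early fusion (both signals
stacked as a 2-channel input to one encoder); late fusion (level-4 concat,
projected to 256 channels); a single fusion module at level 4 only; and
attention-reduced fusion (concatenation only, spatial only, channel only).
Concatenation-only is exactly the full model with both attention branches
forced to identity — an activation-level equality the tests verify under
shared weights.

## Training protocol

Weighted cross-entropy with inverse-frequency class weights
$w_c = N/(K\,N_c)$ (all ones for balanced data), He initialization for
convolution and dense weights, Adam from learning rate 0.01, L2 decay
$10^{-4}$ on convolution/dense weights (value unspecified upstream; chosen
as the conventional default, configurable), batch 32 for training and 128
for evaluation. The learning rate decays ×0.1 whenever the training loss
has not strictly decreased for 5 consecutive epochs (no cooldown — the
streak keeps counting, so decays recur at 10 and 15), and training stops
after 20 such epochs or 100 epochs total. "Did not decrease" is read
literally: strict decrease, zero tolerance (configurable). The schedule is
implemented as a pure state machine, so injected loss traces verify the
rules without any training.

### Batch-norm recalibration on short schedules

Running means/variances start at 0/1 and update with momentum 0.1. On the
short schedules used for desk-scale experiments (tens of optimizer steps)
they lag far behind the weights, so inference-mode accuracy can sit at
chance while the training loss is already low. `train_model` therefore
refreshes them before monitor callbacks and at training end by averaging
batch statistics over a few forward passes (`bn_recal_batches`, default 8)
— weights untouched, a standard recalibration for small-sample batch-norm
models. With the 100-epoch protocol this is immaterial; on short schedules
it removes a pure measurement artifact.

## Missing-modality evaluation

Following the protocol of interest, an absent modality is simulated by
setting that input to zero while the present one is unchanged
(`evaluate_missing_modality`). A zeroed input is far off the training
manifold: the silent branch emits a large constant feature pattern that
shifts the fused representation and hence the softmax threshold. In our
desk-scale experiments this produces a characteristic signature — the AUC
of the degraded model often stays high (the retained modality's information
still modulates the logits) while the *accuracy* at the fixed 0.5 threshold
can collapse toward one class. On subtype-complementary data, where the
theoretical ceiling for a one-modality decision is 75%, we observe
zero-modality accuracies between ~0.60 and 0.75 across seeds at quarter
width and 16-32 training epochs; which side collapses varies with the
seed, and doubling the training length does not reliably close the gap.
Graceful degradation to within a few points of the retained-modality model
therefore appears to require training scales (data volume, epochs, width)
beyond what these shipped experiments use; at desk scale the robust summary
of missing-modality performance is the AUC, not the thresholded accuracy.

## The synthetic-data generator

Real paired recordings cannot ship with the package, so `synth_record()`
simulates the data regime the pipeline targets: 2000 Hz, one ECG and one
PCG channel of equal length, beat-to-beat structure with lognormal
multiplicative RR jitter (strictly positive intervals), and ground-truth S1
onsets at the R peak plus a 50 ms electromechanical delay. The ECG beat is
a sum of five Gaussian deflections (P, Q, R, S, T) at fixed fractions of
the RR interval with the R deflection the global maximum; the PCG beat is
two Gaussian-enveloped cosine bursts (S1 at the annotated onset, where the
envelope peaks; S2 near 38% of RR). Class structure: abnormal beats get an
ST-segment offset (`ecg_effect`) and a 150–400 Hz band-limited systolic
murmur of RMS amplitude `pcg_effect` between S1 and S2. White Gaussian
noise (`noise_sd`) is added per channel. All draws derive from one seed;
identical parameters give bit-identical records.

Defaults model a plausible recording (75 bpm, 5% RR jitter, 40 beats ≈ 32 s,
noise SD 0.05 in units of the R/S1 amplitude, moderate effects 0.3).
Presets fix the study conditions of the package's experiments, chosen once:

* `easy` — effects 1.5, noise 0.02, 10 beats: a regime any working
  implementation should classify almost perfectly; used for the
  learning-capacity check.
* `complementary` — both modalities informative at equal strength
  (effects 0.6) under substantial noise (0.25).
* `ecg_only` / `pcg_only` — the class signal confined to one modality, for
  targeted missing-modality tests.

Injecting the class effect into both modalities of every abnormal record
makes each modality individually *sufficient*, and a gradient-trained fused
model is then free to ignore one of them (the familiar greedy-learner
behaviour of multimodal networks); zeroing the ignored modality costs
nothing and zeroing the used one is catastrophic — the opposite of what a
fusion-ordering experiment needs to measure. The package therefore
operationalizes complementary information with
`synth_complementary_dataset()`: abnormal records split into two equal
subtypes, one expressing only the ST-segment offset (ECG) and one only the
systolic murmur (PCG). On balanced data a single-modality model is capped
near 75% accuracy (it catches its own subtype plus the normals), the fused
model can reach 100%, and it must genuinely use both branches to do so —
which is exactly the regime in which missing-modality degradation is
meaningful to measure.

What the generator does *not* emulate: murmur taxonomy, baseline wander,
respiration, electrode artifacts, inter-subject morphology variation, or
any realistic disease spectrum. Passing tests on this data demonstrate that
the pipeline and network are implemented correctly and can extract
cross-modal structure — not that the architecture reaches any particular
accuracy on clinical recordings.

## Numerical and engineering choices

The network core is implemented in the package itself (reverse-mode tape in
R over Rcpp/Armadillo tensor kernels; convolutions as blocked per-tap BLAS
gemms). Training runs in single precision — standard for this model class —
while a double-precision path exists and is used by the finite-difference
gradient checks in the test suite (12 randomly probed parameters of the
full network agree with central differences at $10^{-4}$). Batch
normalization uses $\epsilon = 10^{-5}$ and momentum 0.1; biased variance
in-batch, unbiased in the running estimate. Degenerate inputs fail loudly:
zero-variance channels, beats shorter than 50 samples, records with fewer
than two S1 onsets, zero class counts, single-class AUC.

## Problem sizes of the shipped experiments

The test-suite and acceptance-script experiments pick sizes a laptop-class
single CPU handles comfortably while still exercising real learning: the
learning-capacity check trains the full-width network on 200 easy records
(1800 one-second segments, 5-fold split) and requires ≥95% held-out
accuracy within 30 epochs, majority of three seeds; the fusion-ordering and
missing-modality experiment runs the architecture at quarter width on
1000-sample cycles (identical topology, reduced widths/length) on 32
subtype-complementary records with 2-fold cross-validation, 16 epochs and
three seeds, comparing fused vs single-modality mean accuracies and the
zero-input degradation (see the missing-modality section for why the
degradation margin is the fragile part of that comparison at this scale). The acceptance script trains the quarter-width
full model and both single-modality branches on 30 easy records and reports
held-out metrics and missing-modality accuracies.

## Known limitations

Segment-level cross-validation can share a subject between train and test
folds when a subject contributed multiple records; the grouping mode
mitigates but cannot recover missing subject identifiers. The WFDB layer
covers single-segment format-16 records (the target layout) rather than the
full format zoo. The simulator's class effects are stationary within a
record, unlike many real pathologies. Accuracy under zeroed-modality
inference is sensitive to training length (threshold bias, see above);
AUC is the more stable summary there.
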