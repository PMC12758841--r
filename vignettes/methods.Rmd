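---
title: "Query-conditioned multimodal fusion for 12-lead ECG diagnosis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Query-conditioned multimodal fusion for 12-lead ECG diagnosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hospital ECG systems produce three kinds of information for every
recording: the raw 12-lead waveform, a small set of machine-measured
summary features (interval timings and electrical axes), and the
patient's demographics. Most deep-learning ECG classifiers consume only
the waveform and discard the structured measurements. `ecgfusion`
implements a multimodal transformer in which the structured features
*query* the waveform: a cross-attention step lets the feature token
retrieve the waveform segments most relevant to it before any joint
encoding happens, and the enriched fusion token then travels through a
standard transformer encoder together with the patch tokens, metadata
tokens and a CLS token whose final state feeds a 13-way multilabel
sigmoid head.

## Model

Let $X_p \in \mathbb{R}^{N_p \times D}$ be the ECG patch tokens (each
non-overlapping 50-sample window across all 12 leads, linearly projected
to $D$ dimensions) and $X_s \in \mathbb{R}^{1 \times D}$ the structured
feature token (9 standardized values concatenated with their 9 validity
bits, passed through a one-hidden-layer GELU network). Fusion is
single-head scaled dot-product cross-attention:

$$
Q = X_s W_Q,\quad K = X_p W_K,\quad V = X_p W_V, \\
A = \mathrm{softmax}\!\left(QK^\top / \sqrt{D}\right),\quad Z = A V, \\
\tilde{X} = \mathrm{LN}\!\left(X_s + \mathrm{FFN}(Z)\right),
$$

where the FFN is one GELU hidden layer of width $D$ and LN is layer
normalization. The attention row $A$ (length $N_p$, summing to 1) is
retained for interpretability. The encoder input is the fixed-order
sequence $[\mathrm{CLS}, \tilde{X}, X_{p,1..N_p}, \mathrm{age},
\mathrm{sex}]$ with learned per-position embeddings; the un-fused
feature token is *not* appended separately — it is consumed by fusion.
Encoding uses pre-norm blocks (multi-head self-attention and a GELU FFN
of width $4D$, both residual, dropout 0.1 on the residual branches
during training). The classification head is a single linear map from
the encoded CLS state to 13 logits in a fixed canonical label order.

Reference dimensions are $D = 768$, 6 layers, 8 heads; every test and
the desk-scale study below run the identical code path at $D = 64$, 2
layers, 2 heads.

Design points that were genuinely open, and what we chose:

* **Metadata tokens.** Age and sex each get their own linear embedding
  (two tokens, `metadata_tokens = 2`); a single joint token and a
  demographics-free variant are configuration options.
* **Positional encoding.** Learned per-position embeddings (the
  ViT/BERT convention), added after assembly including the CLS and
  fusion positions.
* **Fusion head count.** Single-head, matching the fusion equations as
  written; the encoder itself is multi-head.
* **No final layer norm** after the last encoder block, so a zero-depth
  encoder is exactly the identity and the classification head stays a
  pure linear readout.

## Training

The loss is a class-imbalance-aware weighted binary cross-entropy over
the $C = 13$ labels,

$$
\mathcal{L} = -\frac{1}{C}\sum_{c=1}^{C}
\left[\, w_c\, y_c \log \sigma(\hat y_c) +
(1 - y_c) \log\!\big(1 - \sigma(\hat y_c)\big) \right],
\qquad w_c = \frac{N - n_c}{n_c + \varepsilon},
$$

with $N$ the training record count, $n_c$ the positive count of label
$c$, and $\varepsilon = 10^{-6}$ guarding empty labels (a label with no
positives receives an enormous weight that is never exercised, since its
positive term is always zero). Log arguments are clamped at $10^{-12}$.

Optimisation is AdamW (decoupled weight decay 0.01) with global-norm
gradient clipping at 1.0. The forward and backward passes are written in
vectorised base R over BLAS; gradients are validated against central
finite differences in the test suite. After each epoch the **combined
metric** $0.5 \times$ macro AUC $+\,0.5 \times$ macro accuracy (threshold
0.5) on the validation split drives three mechanisms: plateau LR decay
(patience 5 epochs, factor 0.5, relative improvement threshold $10^{-3}$,
cooldown 2), early stopping (patience 10), and best-checkpoint retention
(the returned model is always the epoch with the highest validation
metric, never the last). Batches are reshuffled per epoch from a seeded
stream; validation and test always run in fixed order. Scheduler
constants are defaults, all configurable; no reference values exist for
them.

**Feature-modality dropout.** With probability 0.25 per record and step,
the entire structured-feature input (values and validity bits) is zeroed
during training. This makes the all-features-missing input — which the
prediction interface must serve, and which the feature-masked ablation
probes — an in-distribution case, and it forces the waveform path to
carry diagnostic signal on its own rather than shortcutting through the
features. Without it, a desk-scale model leans almost entirely on the
feature token and collapses under feature masking; with it, masked
inference loses only a few AUC points. This is a training-protocol
choice of this implementation; it changes no inference-time behaviour.

## The synthetic cohort generator

Because the real credentialed hospital cohort cannot ship with a
package, every mechanism is exercised on a synthetic multimodal cohort
whose *shape* mirrors the real data: 12 leads x 5000 samples at 500 Hz,
9 structured features with validity masks, age/sex, multihot labels over
the 13 categories, and strictly increasing acquisition timestamps.

Each record is a Gaussian-bump beat model: P/Q/R/S/T components placed
by the interval timings, projected onto 12 leads by a per-lead gain
vector, over a beat train with log-jittered RR intervals, plus Gaussian
sensor noise (SD 0.03 mV). Disease labels plant stylised *signatures*:
time-localised ST offsets, RR irregularity, PR prolongation, QRS
widening, amplitude scaling, P suppression. Structured features are
computed *from the generator parameters*, not re-measured from the
rendered signal, so feature-level oracles are exact (QTc uses Bazett's
correction; axes come from the frontal-plane projection). Defaults
emulate a large adult hospital population: age 64.8 (SD 17) years,
52.4% male, prevalences led by Normal 39.4%, atrial fibrillation 32.2%
and heart failure 31.9%; "Normal" is mutually exclusive with every
disease label, disease probabilities are solved by a fixed-point
adjustment so empirical marginals still hit their targets after
excluding label-free records, and per-feature missingness is independent
Bernoulli (rate 0.1 by default — a round, realistic figure for
machine-measurement dropout; no reference value exists).

What the generator does *not* emulate: dipole/torso physiology, real
disease morphology, baseline wander and artefacts, label noise, or
temporal distribution drift beyond ordering. A passing synthetic
recovery therefore shows that the architecture, loss, training loop and
evaluation chain are wired correctly and can recover planted,
time-localised structure — not that the model reaches any particular
performance on real ECGs.

## The desk-scale recovery study

`study_config()` fixes the package's end-to-end experiment: 2000
records, three planted signature classes at prevalence 0.25 each
alongside Normal at 0.4, the reduced model ($D = 64$, 2 x 2), 10 epochs
of AdamW at learning rate $4 \times 10^{-4}$, batch 32. The three
planted classes — atrial fibrillation, ST-elevation/non-ST-elevation
myocardial infarction, and supraventricular/ventricular tachycardia —
were chosen because their signatures survive per-lead z-scoring and are
recoverable from the waveform alone (RR timing, ST offset, QRS shape).
That matters for the feature-masking comparison: a class whose signature
lives only in the structured features (e.g. pure PR prolongation) cannot
retain discrimination when the features are masked, which would conflate
"model not robust" with "information not present". Amplitude-scaling
signatures are likewise poor candidates at this scale because per-lead
z-scoring removes absolute gain. Problem sizes (2000 records, 10
epochs) are the package's chosen desk-scale conditions; the study runs
in a few minutes on one CPU core.

## Evaluation and calibration

Per-label AUC is the Mann–Whitney probability with half-credit ties;
AUPRC is step-function average precision with tied scores grouped; the
thresholded metrics (F1, recall, precision, accuracy, specificity) come
from the 2x2 confusion table at probability 0.5 (the conventional
default; no reference threshold exists, and it is configurable). Both
ranking metrics are tested against brute-force pairwise/threshold-walk
oracles. Macro rows report the arithmetic mean and *population* SD
across labels; single-class labels are excluded from the ranking macros
with a warning and flagged in the report. "Accuracy" throughout —
including inside the combined metric — is per-label binary accuracy,
macro-averaged.

Platt calibrators $\sigma(a\hat y + b)$ are fitted per label by
`glm(..., family = binomial)` on the validation split only and applied
unchanged to the test and temporal cohorts, mirroring the no-leakage
rule for feature statistics. Calibration curves use 10 equal-width bins
with empty bins reported at count 0. Subgroup reports stratify by sex or
by age quartile (data-driven boundaries by default; the fixed preset
54/66/78 is available).

Splitting is chronological first — the most recent
$\lceil 0.10\,n \rceil$ records (timestamp order, ties by id) become the
temporally separated test cohort — then a seeded 7:1:1 shuffle of the
development portion (validation and test sizes rounded to nearest,
remainder to train). Feature and age statistics are fitted on the train
split only, use population (1/N) SDs, and carry a split-id tag so
leakage is detectable.

## Interpretability

The exported attention is the single fusion cross-attention row $A$ —
not an encoder self-attention rollout. Patch $i$ anchors to samples
$[(i-1) \cdot 50,\; i \cdot 50)$ and the corresponding 0.1 s of
record time; segments tile the record exactly. The heatmap export
highlights the top 20% of patches by weight (ties to the earliest
patch), a repo convention. On ST-offset-only records the localization
analysis compares mean attention over patches intersecting the planted
ST windows against the background mean with a one-sided sign-flip
permutation test. At desk scale the *polarity* of this localization is
a property of the trained optimum, not of the architecture: early in
training the fusion can transmit ST information either by attending to
elevated patches or by attending to their complement, and short runs
occasionally converge to the anti-localized solution. The positively
localized solution carries the larger gradient (the direct +0.2 mV
offset versus the small z-score-induced baseline shift), so sufficient
training tends to select it; the study schedule was chosen with that in
mind.

## Numerical choices and degenerate inputs

* Population (1/N) SDs everywhere a z-score is taken; a constant lead
  maps to all zeros and a zero-variance feature gets SD 1.
* Layer-norm epsilon $10^{-5}$; GELU uses the tanh approximation.
* Softmax rows subtract their max before exponentiation.
* Non-finite waveform samples are zeroed *before* length fixing;
  truncation and padding act at the end of the record.
* Length fixing is exactly that — no resampling; inputs at other
  sampling rates are out of scope.
* All randomness (cohort, splits, init, shuffling, dropout, permutation
  tests) flows from explicit integer seeds; identical configs are
  bit-reproducible on one machine. Model arguments are forced before
  seeding so lazily evaluated constructors cannot disturb the stream.

## Known limitations

* The generator's missingness is independent per feature; real
  machine-measurement dropout is block-structured per record.
* Synthetic waveforms are stylised; attention heatmaps on them say
  nothing about attention behaviour on real ECGs.
* The temporal split exercises the plumbing of temporal validation, but
  synthetic timestamps carry no distribution drift, so temporal-test
  performance is not a drift probe here.
* Training is single-device, full-precision, and CPU-oriented; there is
  no distributed or mixed-precision path.
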