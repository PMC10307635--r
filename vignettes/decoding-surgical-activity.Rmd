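---
title: "Decoding surgical activity from frame-feature streams: model and methods"
author: "protoact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding surgical activity from frame-feature streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protoact)
```

## The problem

Robot-assisted surgery routinely produces endoscopic video, but the
activity it records — which suturing subphase is being performed
(needle handling, needle driving, needle withdrawal), which discrete
gesture (hook, clip, cold cut, retraction, ...), and how skilfully —
is rarely measured. `protoact` implements a unified decoder of such
activity that operates not on raw pixels but on per-frame feature
vectors produced offline by a frozen spatial feature extractor (e.g. a
self-supervised vision transformer for appearance frames and the same
extractor applied to optical-flow renderings for motion). Decoupling
feature extraction from temporal modelling keeps training cheap and
lets one corpus of stored features serve many decoding tasks.

## The model

Each labelled clip contributes two streams: an appearance sequence and
a motion sequence, each a $T \times D$ matrix of frame features
(default $D = 384$). A single transformer encoder — its parameters
shared across the two modalities to limit overfitting — processes each
stream:

1. a learned classification token $e_{cls} \in \mathbb{R}^D$ is
   prepended and learned temporal positional embeddings are added to
   the frame features;
2. the sequence passes through $L$ encoder layers (default 4) of
   masked multi-head self-attention and a position-wise feed-forward
   network, with residual connections and layer normalization;
3. the classification-token representation at the final layer,
   $h_{cls} \in \mathbb{R}^D$, summarizes the stream.

The two modality summaries are aggregated by elementwise addition,
$h_{agg} = h_{RGB} + h_{Flow}$, and projected by two linear maps with
a ReLU between them to a video representation
$h_{video} \in \mathbb{R}^E$ (default $E = 256$).

Classification is prototype based. A bank holds one learnable
prototype $p_j \in \mathbb{R}^E$ per category. Training minimizes the
supervised contrastive (InfoNCE) objective

$$\mathcal{L} = -\sum_{i=1}^{B} \log
  \frac{e^{s(h_i, p_{c_i})}}{\sum_j e^{s(h_i, p_j)}},
  \qquad s(h, p) = \frac{h \cdot p}{\lVert h \rVert \lVert p \rVert},$$

summed over the mini-batch as written, with no temperature: the
exponent is the raw cosine similarity. At evaluation time the softmax
of the cosine similarities is the predicted probability mass and the
argmax (ties broken by lowest category index) the label. Everything —
encoder, token and positional embeddings, projection head, prototypes
— is trained end to end by plain SGD (defaults: batch size 8, learning
rate 0.1).

Because the exponentiated scores are cosines, which live in
$[-1, 1]$, the output mass is deliberately soft: with $C = 6$
categories even a perfectly classified sample has entropy around
1.3–1.65 nats against a uniform-mass ceiling of $\ln 6 \approx 1.79$.
This matters for the abstention rule below.

### Variable-length batches

Clips have different lengths, so batches are padded with all-zero
placeholder rows to the batch maximum and a mask marks the padding.
Padded rows are excluded from attention as keys, and layer
normalization acts row-wise, so a padded row can never influence the
classification token: `encodeModality()` of a padded sample equals
that of the original to machine precision. The test suite asserts this
invariance directly rather than trusting it.

### Ablation switches

The configuration exposes the model's own ablations:
`use_self_attention = FALSE` replaces the encoder with a mean over
valid frame features (the projection and prototypes still apply);
`modalities` restricts input to one stream, with the missing summary
entering the aggregation as a zero vector. The projection head is
applied to $h_{agg}$ in all variants.

### Explanation

`frameImportance()` reports the attention placed by the
classification token on each frame in the final encoder layer,
averaged over heads and the two modality streams and renormalized over
valid frames. The layer/head choice is a package decision — the
mechanism is only specified as "the attention on frames" — and is the
conventional one for transformer classifiers.

## Training protocol

Evaluation uses video-level Monte Carlo cross-validation: each of the
(default ten) folds independently samples 10% of the *videos* as a
test set and 10% of the remaining pool for validation, so no clip of a
test video is ever seen during training — generalization is measured
across videos, not across clips of the same video. Skill-style tasks
additionally class-balance the training set by downsampling every
category to the minimum category count. Epoch count and model
selection are not prescribed by the protocol we follow; the package
defaults to 50 epochs and keeps the checkpoint with the lowest
validation loss (small heads converge quickly; the desk-scale studies
below use 6–8 epochs). Fold seeds are derived from the base seed plus
the fold id, so every split, initialization and shuffle is
reproducible.

## Frame selection

Sampling rules are task specific. Gesture clips contribute ten equally
spaced frames, index $k \lfloor (n-1)/9 \rfloor$ for $k = 0..9$ (a
90-frame clip yields 0, 9, 18, ..., 81); subphase and skill clips
contribute every tenth frame (0, 10, 20, ...). Clips with fewer than
ten frames fall back to all frames under the gesture rule, with a
message. Motion (optical-flow) frames are paired with appearance
frames at a separation of `round(fps * flow_dt)` frames (default 0.5
s), one flow map aligned per retrieved appearance frame; the map
stride within a clip is a package decision, since only the pair
separation is prescribed.

## Full-video inference

To decode an unannotated video the package:

1. **curates windows** — subphase regime: 10-s windows stepping by 5 s
   *plus* 5-s windows stepping by 5 s (the overlap captures boundary
   activity; the short windows capture brief subphases); gesture
   regime: 1-s non-overlapping windows;
2. **builds three test-time inputs** per window by offsetting the
   sampling grid's start frame by 0, 3 and 6 frames;
3. **scores** every input with every fold's model;
4. **bags**: all probabilistic outputs for a 10-s timespan on the 5-s
   grid are averaged. An approach-1 window feeds the timespan sharing
   its start; a 5-s window feeds the (up to two) 10-s timespans
   containing it, so an interior timespan accumulates
   $3 \times 10 \times 3 = 90$ outputs under the full configuration.
   Timespans at the video edges average over whatever cells exist. We
   average rather than sum — equivalent for the argmax, and required
   for the entropy below to be well defined;
5. **abstains** when the natural-log entropy of the bagged mass
   strictly exceeds `S_thresh`. The gesture-regime default is 1.74, an
   operating point reported for six-category gesture decoding; it is
   specific to $C = 6$ (for seven categories the entropy of even a
   confident cosine-softmax mass exceeds it). For other category
   counts the package default is $0.95 \ln C$ — a package choice, not
   a published value — and the threshold is configurable;
6. **chains** kept predictions: same-category predictions whose gap is
   strictly less than `chain_gap` (default 3 s for subphases, 2 s for
   gestures) merge into one event, overlaps being unioned first.
   Chaining is idempotent and different categories never merge.

`activityProfile()` turns decoded events plus per-event skill labels
into a per-case timeline and low-skill ratio.

## Evaluation metrics

One-vs-rest ROC AUC (via pROC, trapezoidal tie handling) per category
with macro averaging; positive predictive value per category; and
segmental F1@k for temporal segmentation, with k an
intersection-over-union threshold (reported on a 0–100 scale, default
k = 0.10). The F1@k matching follows the temporal-action-segmentation
convention: predictions are matched greedily by decreasing IoU, each
ground-truth segment used at most once. Per-video scores are averaged
across videos where applicable.

## Outcome association

`fitOutcomeModel()` regresses a binary patient outcome (e.g. urinary
continence recovery three months after surgery) on the decoded
high-skill probability $Z_1$, adjusting for surgeon caseload $Z_2$ and
patient age $Z_3$, with maximum-likelihood logistic regression:
$Y = \sigma(b_0 + b_1 Z_1 + b_2 Z_2 + b_3 Z_3)$. The odds ratio
$e^{b_1}$ is reported with a Wald 95% interval. Per-sample fits do not
adjust standard errors for within-case correlation — a documented
limitation mirroring the unadjusted variant of the analysis;
`aggregateCase()` provides the per-case variant by averaging $Z_1$
within each case.

## Synthetic data: what it emulates and what it does not

No public corpus of surgical frame features exists, so the package
ships a generator used by every test. Each category is assigned a
fixed unit mean direction in feature space (a pure function of the
config seed). An appearance frame is the category direction scaled by
`snr` plus AR(1) noise of unit stationary variance (default
coefficient 0.8, emulating the temporal smoothness of video); a motion
frame is `modality_correlation` (default 0.7) times the appearance
frame plus independent AR(1) noise. Timelines repeat an ordered motif
— by default hook, then clip, then cold cut, the recurring
nerve-sparing dissection pattern — with event durations and background
gaps drawn from configured ranges, and return ground-truth intervals
alongside the streams.

The generator reproduces the *statistical* structure the model
assumes: class-conditional means, temporal smoothness, correlated
modalities, labelled intervals. It does not emulate anatomy-dependent
appearance drift, surgeon-specific styles, camera motion, annotation
noise, or the long-tailed duration distributions of real surgery, so
passing tests demonstrate correctness of the machinery, not clinical
performance.

A designated `background` category (zero mean direction) generates
content statistically identical to inter-event background. The
timeline studies train closed-world — motif classes plus background —
and drop background-labelled windows before chaining. This is the
standard device in temporal action segmentation, and it is necessary
here: entropy abstention alone cannot reject out-of-vocabulary
background at desk scale, because the cosine-softmax entropy range is
narrow and a zero-mean background window still projects substantially
onto prototype directions (we measured bagged background entropies
straddling 1.74 at both $D = 32$ and $D = 128$, with 3 and 10 folds).
Abstention remains responsible for ambiguous and boundary windows.

## Study conditions used by the tests

Chosen once, as realistic desk-scale conditions, and stated here as
package choices:

* **Clip recovery:** four gesture categories, $D = 32$ (the test
  default; full-size runs use 384), $E = 32$, one encoder layer, four
  heads, dropout 0.1, 40 videos of 10 clips each (400 clips), ten
  Monte Carlo folds, 8 epochs, `snr` 5 and 0. At `snr = 5` a linear
  probe on mean frame vectors is already near-perfect; the test
  requires the full pipeline to reach macro AUC at least 0.95, and
  `snr = 0` to stay at chance within 0.05.
* **Timeline recovery:** categories hook/clip/cold-cut/background,
  `snr = 5`, durations 1–4 s, gaps 3–8 s, a 30-video training corpus,
  ten folds, 6 epochs, a 600-s timeline, threshold $0.95 \ln 4$. The
  decoder must recover at least 90% of planted events at IoU 0.1 with
  segmental F1 above 80.
* **Outcome cohort:** $n = 2000$, known $b_1$; the fitted odds ratio
  must land within two standard errors of the truth, and a null
  $b_1 = 0$ must give an odds ratio of one within its interval.

## Numerical choices and degenerate inputs

* Layer normalization uses $\epsilon = 10^{-5}$; attention scores are
  scaled by $1/\sqrt{D/H}$; weights are Glorot-uniform, embeddings
  $\mathcal{N}(0, 0.02^2)$, prototypes $\mathcal{N}(0, 1/E)$.
* Gradients of the whole network are hand-derived and checked against
  central finite differences in the test suite (relative error below
  $10^{-4}$ on every parameter group with non-vanishing gradient).
* Cosine similarity is undefined for zero-norm embeddings or
  prototypes and raises an error rather than returning a silent
  default; at very small $E$ a freshly initialized ReLU head can emit
  an exactly-zero embedding, which surfaces as this error.
* Entropy uses the $0 \log 0 = 0$ convention; abstention is strict
  (`entropy > S_thresh`), so a uniform six-category mass
  ($\ln 6 \approx 1.792$) abstains at 1.74 while any one-hot mass
  (entropy 0) is kept.
* Argmax ties break toward the lowest category index, for determinism.
* Sequences longer than the positional capacity `max_T` (default 512)
  raise a capacity error rather than truncating silently.

## Known limitations

The encoder is plain R (BLAS-backed matrix arithmetic); it is sized
for the desk-scale studies above, not for GPU-scale corpora. Frame
features must be produced by an external extractor — the package
defines the store format and sampling rules but deliberately does not
bundle a spatial feature extractor or an optical-flow estimator.
Reported clinical operating points (AUCs on private hospital data,
the 1.74 threshold) are properties of the original private corpora
and are not reproduced by the synthetic studies.
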