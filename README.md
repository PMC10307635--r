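# protoact

Decoding what a surgeon does — and how well — from surgical video,
without touching raw pixels. `protoact` implements a unified,
prototype-based temporal-transformer classifier over *per-frame
feature streams*: appearance ("RGB") and motion (optical-flow)
features extracted once, offline, by a frozen spatial backbone and
stored for reuse. One architecture decodes suturing subphases (needle
handling / driving / withdrawal), discrete gestures (hook, clip, cold
cut, ...) and binary skill levels, and the package carries the method
through to full-length, unannotated videos and to patient-outcome
association. It is aimed at surgical data-science groups working with
robot-assisted procedure video.

## The model

Each labelled clip supplies two sequences of frame features
(T x D per modality). A transformer encoder with parameters shared
across modalities prepends a learnable classification token, adds
learned temporal positional embeddings, applies masked multi-head
self-attention (zero-padded frames are never attended to), and reads
out the classification token h_cls of each stream. The streams are
fused by addition and projected:

    h_agg   = h_RGB + h_Flow
    h_video = W2 ReLU(W1 h_agg + b1) + b2        (h_video in R^E)

Classification is by softmax over cosine similarities to one learnable
prototype p_j per category. Training minimizes the supervised
contrastive (InfoNCE) loss, summed over the mini-batch, with the raw
cosine as the exponent:

    L = - sum_i log [ exp(s(h_i, p_c_i)) / sum_j exp(s(h_i, p_j)) ],
    s(h, p) = h . p / (|h| |p|)

Everything is trained end to end by SGD (batch 8, learning rate 0.1 by
default), evaluated with video-level Monte Carlo cross-validation so
test clips always come from unseen videos.

Full-video inference combines sliding windows (10-s overlapping plus
5-s windows for subphases; 1-s windows for gestures), three test-time
augmentations per window (start-frame offsets 0/3/6), bagging of all
probabilistic outputs per 10-s timespan across windows, folds and
augmentations (3 x 10 x 3 = 90 for an interior timespan), entropy
abstention (natural log; gesture default threshold 1.74), and chaining
of same-category predictions less than 2 s (gestures) or 3 s
(subphases) apart into events.

All of this — model, training loop and hand-derived backpropagation —
is implemented in plain R on top of BLAS matrix arithmetic; gradients
are verified against finite differences in the test suite.

## Worked example

Simulate a small gesture corpus, train one Monte Carlo fold, and
inspect a held-out prediction:

```r
library(protoact)

cfg <- syntheticConfig(categories = c("hook", "cold_cut"), D = 32, snr = 5,
                       seed = 11, duration_range = c(1, 3))
corpus <- genClipSet(cfg, nVideos = 12, clipsPerVideo = 6,
                     task = "gesture", seed = 11)

splits <- makeSplits(unique(corpus$annotations$video_id), nFolds = 1, seed = 11)
enc <- encoderConfig(D = 32, E = 32, n_layers = 1, n_heads = 4,
                     max_T = 16, dropout = 0.1)
model <- trainFold(corpus$samples, splits[[1]], enc,
                   trainConfig(n_epochs = 5, seed = 11))
model
#> ActivityDecoder: D=32, E=32, 1 encoder layer(s), 4 head(s), 2 categories
#>   trained 5 epochs; best validation loss 0.1280

preds <- predictFold(corpus$samples, splits[[1]], model)
rocAUC(as.matrix(preds[, model@categories]), preds$label)$macro
#> [1] 1

s <- corpus$samples[[which(vapply(corpus$samples, videoId, character(1)) %in%
                           splits[[1]]$test)[1]]]
round(predictSample(s, model), 3)
#>  cold_cut     hook
#>      0.12     0.88        (label: "hook")
round(frameImportance(s, model), 3)
#>  [1] 0.099 0.102 0.098 0.098 0.100 0.100 0.100 0.102 0.101 0.100
```

The held-out clip is classified as a hook with probability 0.88 — note
the deliberately soft masses produced by the cosine-similarity softmax
— and the attention-based frame weights show the toy model spreading
its attention nearly uniformly over the ten sampled frames. The
one-fold macro AUC of 1 reflects the high separation (snr = 5) of this
small synthetic corpus.

For full-video decoding see `decodeVideo()`, and for the pipeline
entry point (`simulate`, `train`, `infer`, `evaluate`, `explain`,
`outcomes`) see `runPipeline()` or the thin CLI in
`inst/scripts/protoact`. The methods vignette
(`vignettes/decoding-surgical-activity.Rmd`) documents the model,
the inference machinery, the synthetic-data generator and all
numerical choices.

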