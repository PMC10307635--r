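#' Create an (untrained) activity decoder
#'
#' Initializes all learnable parameters — classification-token
#' embedding, temporal positional embeddings, shared encoder layers,
#' projection head and category prototypes — from the current RNG
#' stream.
#'
#' @param config an [encoderConfig()].
#' @param categories character vector of category labels (>= 2).
#' @param seed optional integer seed for reproducible initialization.
#' @return An [ActivityDecoder-class].
#' @export
newActivityDecoder <- function(config, categories, seed = NULL) {
  stopifnot(inherits(config, "encoderConfig"))
  categories <- as.character(categories)
  if (length(categories) < 2) stop("at least two categories are required")
  if (!is.null(seed)) set.seed(seed)
  params <- .initParams(config, length(categories))
  new("ActivityDecoder",
    params = params, config = unclass(config), categories = categories,
    history = data.frame(epoch = integer(), train_loss = numeric(),
                         val_loss = numeric())
  )
}

.decoderConfig <- function(model) {
  cfg <- model@config
  class(cfg) <- "encoderConfig"
  cfg
}

#' Encode one modality stream
#'
#' Runs one [FrameFeatureSequence-class] through the shared temporal
#' transformer encoder and returns the classification-token
#' representation at the final layer. Padded frames are excluded from
#' attention, so appending padding never changes the result. With
#' \code{use_self_attention = FALSE} (ablation) the mean of the valid
#' frame features is returned instead.
#'
#' @param seq a [FrameFeatureSequence-class].
#' @param model an [ActivityDecoder-class].
#' @return A length-D numeric vector.
#' @export
encodeModality <- function(seq, model) {
  stopifnot(is(seq, "FrameFeatureSequence"), is(model, "ActivityDecoder"))
  .encoderForward(seq@vectors, seq@validMask, model@params,
                  .decoderConfig(model))$h
}

#' Aggregate the two modality summaries
#'
#' The appearance and motion stream summaries are combined by
#' elementwise addition; in single-modality ablations the missing stream
#' is the zero vector.
#'
#' @param hRgb,hFlow length-D numeric vectors.
#' @return Their elementwise sum.
#' @export
aggregateModalities <- function(hRgb, hFlow) {
  if (length(hRgb) != length(hFlow))
    stop("modality summaries have different lengths")
  hRgb + hFlow
}

#' Project an aggregated representation to the prototype space
#'
#' Two linear maps with a rectifier (ReLU) between them take the
#' aggregated D-dimensional representation to the E-dimensional space in
#' which prototypes live.
#'
#' @param hAgg length-D numeric vector.
#' @param model an [ActivityDecoder-class].
#' @return A length-E numeric vector.
#' @export
projectEmbedding <- function(hAgg, model) {
  stopifnot(is(model, "ActivityDecoder"))
  .stopifnotFinite(hAgg, "hAgg")
  p <- model@params
  if (length(hAgg) != nrow(p$P1)) stop("input length must equal D")
  a <- pmax(drop(hAgg %*% p$P1) + p$c1p, 0)
  drop(a %*% p$P2) + p$c2p
}

#' Classify a video embedding against the prototype bank
#'
#' Computes the cosine similarity of the embedding to every prototype
#' and applies the softmax, yielding a probability mass over categories.
#' The predicted label is the argmax (ties broken by the lowest category
#' index).
#'
#' @param hVideo length-E numeric vector (nonzero).
#' @param bank a [PrototypeBank-class].
#' @return Named numeric probability vector with attribute
#'   \code{"label"} holding the predicted category.
#' @export
classifyEmbedding <- function(hVideo, bank) {
  stopifnot(is(bank, "PrototypeBank"))
  P <- bank@prototypes
  sims <- vapply(seq_len(nrow(P)), function(j) .cosine(hVideo, P[j, ]),
                 numeric(1))
  probs <- .softmaxVec(sims)
  names(probs) <- bank@categoryNames
  attr(probs, "label") <- bank@categoryNames[which.max(probs)]
  probs
}

#' Supervised contrastive (InfoNCE) loss over prototypes
#'
#' For each embedding h_i with category c_i the per-sample term is
#' \code{-log( exp(s(h_i, p_{c_i})) / sum_j exp(s(h_i, p_j)) )} where s
#' is the cosine similarity (no temperature; the exponent is the raw
#' cosine). The loss is the sum of these terms over the batch.
#'
#' @param H B x E matrix of video embeddings (rows nonzero).
#' @param labels length-B character vector of categories; each must have
#'   a prototype in \code{bank}.
#' @param bank a [PrototypeBank-class].
#' @return Nonnegative scalar loss.
#' @export
infoNCELoss <- function(H, labels, bank) {
  stopifnot(is(bank, "PrototypeBank"))
  H <- rbind(H)
  if (nrow(H) != length(labels)) stop("one label per embedding is required")
  ci <- match(labels, bank@categoryNames)
  if (anyNA(ci))
    stop(sprintf("label(s) without a prototype: %s",
                 paste(unique(labels[is.na(ci)]), collapse = ", ")))
  .infoNCE(H, ci, bank@prototypes)$loss
}

# InfoNCE loss plus gradients w.r.t. embeddings and prototypes.
.infoNCE <- function(H, classIdx, proto) {
  B <- nrow(H); C <- nrow(proto)
  nh <- sqrt(rowSums(H^2))
  np <- sqrt(rowSums(proto^2))
  if (any(nh == 0) || any(np == 0))
    stop("cosine similarity undefined for a zero-norm vector")
  S <- (H %*% t(proto)) / (nh %o% np)           # B x C cosines
  Q <- .softmaxRows(S)
  loss <- -sum(log(Q[cbind(seq_len(B), classIdx)]))
  dS <- Q
  dS[cbind(seq_len(B), classIdx)] <- dS[cbind(seq_len(B), classIdx)] - 1
  # d cos(h, p)/dh = p/(|h||p|) - cos * h/|h|^2 ; symmetric in p
  dH <- matrix(0, B, ncol(H))
  dP <- matrix(0, C, ncol(proto))
  for (i in seq_len(B)) {
    h <- H[i, ]
    w <- dS[i, ]
    dH[i, ] <- drop((w / np) %*% proto) / nh[i] -
      (sum(w * S[i, ]) / nh[i]^2) * h
    dP <- dP + (w / (nh[i] * np)) %o% h -
      ((w * S[i, ]) / np^2) * proto
  }
  list(loss = loss, S = S, Q = Q, dH = dH, dP = dP)
}

# Full forward pass for one sample: encode both streams, aggregate,
# project. Returns h_video plus caches for the backward pass.
.sampleForward <- function(sample, params, cfg, train = FALSE,
                           keepCache = FALSE) {
  D <- cfg$D
  useApp <- "appearance" %in% cfg$modalities
  useMot <- "motion" %in% cfg$modalities
  encA <- if (useApp) {
    .encoderForward(sample@appearance@vectors, sample@appearance@validMask,
                    params, cfg, train = train, keepCache = keepCache)
  } else list(h = numeric(D), cache = NULL, clsAttention = NULL)
  encM <- if (useMot) {
    .encoderForward(sample@motion@vectors, sample@motion@validMask,
                    params, cfg, train = train, keepCache = keepCache)
  } else list(h = numeric(D), cache = NULL, clsAttention = NULL)
  hAgg <- encA$h + encM$h
  u <- drop(hAgg %*% params$P1) + params$c1p
  a <- pmax(u, 0)
  hVideo <- drop(a %*% params$P2) + params$c2p
  list(hVideo = hVideo, hAgg = hAgg, a = a, u = u, encA = encA, encM = encM)
}

# Backward pass matching .sampleForward; accumulates into grads.
.sampleBackward <- function(dHVideo, fw, sample, params, cfg, grads) {
  grads$P2 <- grads$P2 + fw$a %o% dHVideo
  grads$c2p <- grads$c2p + dHVideo
  da <- drop(params$P2 %*% dHVideo)
  du <- da * (fw$u > 0)
  grads$P1 <- grads$P1 + fw$hAgg %o% du
  grads$c1p <- grads$c1p + du
  dHAgg <- drop(params$P1 %*% du)
  if (cfg$use_self_attention) {
    if (!is.null(fw$encA$cache))
      grads <- .encoderBackward(dHAgg, fw$encA$cache, params, cfg, grads)$grads
    if (!is.null(fw$encM$cache))
      grads <- .encoderBackward(dHAgg, fw$encM$cache, params, cfg, grads)$grads
  }
  grads
}

#' Per-frame importance from the attention mechanism
#'
#' Attention placed by the classification token on each frame in the
#' final encoder layer, averaged over heads and over the two modality
#' streams, renormalized over valid frames. High-attention frames are
#' the ones driving the decoding (e.g. needle repositions in a low-skill
#' needle-handling clip).
#'
#' @param sample a [VideoSample-class] with at least one valid frame.
#' @param model a trained [ActivityDecoder-class].
#' @return Numeric vector with one weight per frame of the sample
#'   (padded frames get 0); weights over valid frames sum to 1.
#' @export
frameImportance <- function(sample, model) {
  stopifnot(is(sample, "VideoSample"), is(model, "ActivityDecoder"))
  cfg <- .decoderConfig(model)
  if (!cfg$use_self_attention)
    stop("frame importance requires the self-attention encoder (use_self_attention = TRUE)")
  acc <- NULL
  n <- 0L
  for (mod in cfg$modalities) {
    seq <- if (mod == "appearance") sample@appearance else sample@motion
    enc <- .encoderForward(seq@vectors, seq@validMask, model@params, cfg)
    w <- enc$clsAttention[-1L]            # drop attention to the cls token
    w[!seq@validMask] <- 0
    if (is.null(acc)) acc <- w else acc <- acc + w
    n <- n + 1L
  }
  w <- acc / n
  s <- sum(w)
  if (s <= 0) stop("no attention mass on valid frames")
  w / s
}

#' Classify a video sample
#'
#' Convenience wrapper: encodes both streams, aggregates, projects and
#' classifies against the model's prototypes.
#'
#' @param sample a [VideoSample-class].
#' @param model an [ActivityDecoder-class].
#' @return Named probability vector as in [classifyEmbedding()].
#' @export
predictSample <- function(sample, model) {
  fw <- .sampleForward(sample, model@params, .decoderConfig(model))
  classifyEmbedding(fw$hVideo, prototypeBank(model))
}

#' Save or load a decoder checkpoint
#'
#' Checkpoints contain the full parameter set, the encoder
#' configuration, the category labels, the training history and a
#' format version.
#'
#' @param model an [ActivityDecoder-class].
#' @param path file path.
#' @return \code{loadCheckpoint} returns the [ActivityDecoder-class].
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "ActivityDecoder"))
  saveRDS(list(format = "protoact-checkpoint-1", params = model@params,
               config = model@config, categories = model@categories,
               history = model@history), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "protoact-checkpoint-1"))
    stop("not a recognized checkpoint file")
  new("ActivityDecoder", params = x$params, config = x$config,
      categories = x$categories, history = x$history)
}
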