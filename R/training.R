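#' Training configuration
#'
#' @param batch_size mini-batch size (default 8).
#' @param learning_rate SGD learning rate (default 0.1).
#' @param n_epochs training epochs (default 50); the checkpoint with the
#'   best validation loss is kept.
#' @param seed base RNG seed.
#' @param class_balanced downsample every category to the minimum
#'   category count before training (default \code{TRUE}).
#' @return A validated list of class \code{"trainConfig"}.
#' @export
trainConfig <- function(batch_size = 8L, learning_rate = 0.1,
                        n_epochs = 50L, seed = 1L, class_balanced = TRUE) {
  cfg <- list(batch_size = as.integer(batch_size),
              learning_rate = as.numeric(learning_rate),
              n_epochs = as.integer(n_epochs), seed = as.integer(seed),
              class_balanced = isTRUE(class_balanced))
  if (cfg$batch_size < 1) stop("batch_size must be >= 1")
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive")
  if (cfg$n_epochs < 1) stop("n_epochs must be >= 1")
  class(cfg) <- "trainConfig"
  cfg
}

#' Video-level Monte Carlo cross-validation splits
#'
#' Each fold independently samples 10% of the videos as a test set and
#' 10% of the remaining training pool as a validation set; the rest
#' train. Splitting at the video level means no clip of a test video is
#' ever seen in training, so test performance measures generalization to
#' unseen videos.
#'
#' @param videoIds character vector of all video identifiers (>= 3).
#' @param nFolds number of Monte Carlo folds (default 10).
#' @param seed base seed; fold f uses a seed derived from
#'   \code{seed + f} so splits are reproducible.
#' @param testFrac,valFrac sampling fractions (defaults 0.1 and 0.1).
#' @return List of \code{nFolds} lists with elements \code{fold_id},
#'   \code{train}, \code{val}, \code{test} (disjoint video-id sets) and
#'   \code{seed}.
#' @export
makeSplits <- function(videoIds, nFolds = 10L, seed = 1L,
                       testFrac = 0.1, valFrac = 0.1) {
  videoIds <- unique(as.character(videoIds))
  n <- length(videoIds)
  if (n < 3) stop("at least 3 videos are required to form train/val/test sets")
  nTest <- max(1L, round(testFrac * n))
  nVal <- max(1L, round(valFrac * (n - nTest)))
  if (n - nTest - nVal < 1)
    stop("too few videos for a nonempty training set")
  lapply(seq_len(nFolds), function(f) {
    set.seed(.deriveSeed(seed, f))
    test <- sample(videoIds, nTest)
    pool <- setdiff(videoIds, test)
    val <- sample(pool, nVal)
    train <- setdiff(pool, val)
    list(fold_id = f, train = train, val = val, test = test,
         seed = .deriveSeed(seed, f))
  })
}

#' Write split manifests as TSV
#'
#' @param splits output of [makeSplits()].
#' @param path TSV path; columns \code{fold_id}, \code{video_id},
#'   \code{set}.
#' @export
writeSplits <- function(splits, path) {
  rows <- do.call(rbind, lapply(splits, function(sp) {
    do.call(rbind, lapply(c("train", "val", "test"), function(s) {
      if (!length(sp[[s]])) return(NULL)
      data.frame(fold_id = sp$fold_id, video_id = sp[[s]], set = s,
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Class-balance a set of labelled samples
#'
#' Downsamples every category to the minimum category count, so each
#' category contributes the same number of samples (as used for skill
#' assessment, where low- and high-skill sets are equalized).
#'
#' @param samples list of [VideoSample-class] objects with labels.
#' @param seed RNG seed for the (deterministic) downsampling.
#' @return Sub-list of \code{samples}.
#' @export
balanceClasses <- function(samples, seed = 1L) {
  labels <- vapply(samples, category, character(1))
  if (anyNA(labels)) stop("all samples must be labelled")
  counts <- table(labels)
  if (length(counts) < 2) stop("class balancing requires at least two categories")
  m <- min(counts)
  set.seed(.deriveSeed(seed, 97L))
  keep <- unlist(lapply(names(counts), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) > m) sample(idx, m) else idx
  }))
  samples[sort(keep)]
}

#' Collate a mini-batch of variable-length samples
#'
#' Pads every sequence with all-zero placeholder rows to the batch
#' maximum length and records an attention mask that is \code{FALSE}
#' exactly on padded rows, so the encoder never attends to padding.
#'
#' @param samples list of [VideoSample-class] objects.
#' @return List with \code{appearance} and \code{motion} (B x Tmax x D
#'   arrays), \code{mask} (B x Tmax logical), \code{labels} and
#'   \code{samples} (the padded [VideoSample-class] objects).
#' @export
collateBatch <- function(samples) {
  Ts <- vapply(samples, function(s) nFrames(s@appearance), integer(1))
  Tmax <- max(Ts)
  B <- length(samples)
  D <- ncol(featureMatrix(samples[[1]]@appearance))
  app <- array(0, c(B, Tmax, D))
  mot <- array(0, c(B, Tmax, D))
  mask <- matrix(FALSE, B, Tmax)
  padded <- vector("list", B)
  for (i in seq_len(B)) {
    s <- samples[[i]]
    padded[[i]] <- .padSample(s, Tmax)
    app[i, , ] <- featureMatrix(padded[[i]]@appearance)
    mot[i, , ] <- featureMatrix(padded[[i]]@motion)
    mask[i, ] <- validMask(padded[[i]]@appearance)
  }
  list(appearance = app, motion = mot, mask = mask,
       labels = vapply(samples, category, character(1)), samples = padded)
}

# Pad both streams of a sample with zero rows up to length Tmax.
.padSample <- function(s, Tmax) {
  padSeq <- function(fs) {
    Tn <- nFrames(fs)
    if (Tn >= Tmax) return(fs)
    extra <- Tmax - Tn
    v <- rbind(fs@vectors, matrix(0, extra, ncol(fs@vectors)))
    lastIdx <- if (Tn > 0) fs@frameIndices[Tn] else -1L
    FrameFeatureSequence(v, fs@modality,
      frameIndices = c(fs@frameIndices, lastIdx + seq_len(extra)),
      fps = fs@fps, validMask = c(fs@validMask, rep(FALSE, extra)))
  }
  new("VideoSample", videoId = s@videoId, startS = s@startS, endS = s@endS,
      category = s@category, appearance = padSeq(s@appearance),
      motion = padSeq(s@motion))
}

# One SGD step on a mini-batch; returns updated params and the batch loss.
.trainStep <- function(samples, labels, params, cfg, classIdx, lr) {
  B <- length(samples)
  fws <- vector("list", B)
  H <- matrix(0, B, cfg$E)
  for (i in seq_len(B)) {
    fws[[i]] <- .sampleForward(samples[[i]], params, cfg,
                               train = TRUE, keepCache = TRUE)
    H[i, ] <- fws[[i]]$hVideo
  }
  nce <- .infoNCE(H, classIdx, params$proto)
  grads <- .zeroLike(params)
  grads$proto <- grads$proto + nce$dP
  for (i in seq_len(B)) {
    grads <- .sampleBackward(nce$dH[i, ], fws[[i]], samples[[i]],
                             params, cfg, grads)
  }
  list(params = .sgdStep(params, grads, lr), loss = nce$loss)
}

# Mean InfoNCE loss of a sample set in evaluation mode.
.evalLoss <- function(samples, labels, params, cfg, categories) {
  H <- t(vapply(samples, function(s)
    .sampleForward(s, params, cfg)$hVideo, numeric(cfg$E)))
  .infoNCE(H, match(labels, categories), params$proto)$loss / length(samples)
}

#' Train one cross-validation fold
#'
#' Trains the encoder, classification-token and positional embeddings,
#' projection head and prototypes end-to-end by SGD on the prototype
#' InfoNCE objective, selecting the epoch with the lowest validation
#' loss. Deterministic given the seeds in \code{split} and
#' \code{trainCfg}.
#'
#' @param samples list of labelled [VideoSample-class] objects.
#' @param split one element of [makeSplits()] output.
#' @param encoderCfg an [encoderConfig()].
#' @param trainCfg a [trainConfig()].
#' @param categories optional fixed category ordering; defaults to the
#'   sorted labels present in the training set.
#' @param verbose print per-epoch losses.
#' @return A trained [ActivityDecoder-class]; its \code{history} slot
#'   holds per-epoch mean train/validation loss.
#' @export
trainFold <- function(samples, split, encoderCfg, trainCfg = trainConfig(),
                      categories = NULL, verbose = FALSE) {
  stopifnot(inherits(encoderCfg, "encoderConfig"),
            inherits(trainCfg, "trainConfig"))
  vids <- vapply(samples, videoId, character(1))
  trainSet <- samples[vids %in% split$train]
  valSet <- samples[vids %in% split$val]
  if (!length(trainSet) || !length(valSet))
    stop("split produced an empty training or validation set")
  seed <- .deriveSeed(trainCfg$seed, split$fold_id)
  if (trainCfg$class_balanced) trainSet <- balanceClasses(trainSet, seed = seed)
  labels <- vapply(trainSet, category, character(1))
  if (is.null(categories)) categories <- sort(unique(labels))
  valLabels <- vapply(valSet, category, character(1))
  if (!all(valLabels %in% categories))
    stop("validation set contains categories absent from training")
  set.seed(seed)
  cfg <- unclass(encoderCfg)
  params <- .initParams(cfg, length(categories))
  classIdxAll <- match(labels, categories)
  n <- length(trainSet)
  B <- trainCfg$batch_size
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  for (ep in seq_len(trainCfg$n_epochs)) {
    ord <- sample(n)
    epochLoss <- 0
    for (b in seq_len(ceiling(n / B))) {
      idx <- ord[((b - 1L) * B + 1L):min(b * B, n)]
      st <- .trainStep(trainSet[idx], labels[idx], params, cfg,
                       classIdxAll[idx], trainCfg$learning_rate)
      params <- st$params
      epochLoss <- epochLoss + st$loss
    }
    vl <- .evalLoss(valSet, valLabels, params, cfg, categories)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = epochLoss / n,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %d: train %.4f, val %.4f", ep, epochLoss / n, vl))
    if (vl < best$loss) best <- list(loss = vl, params = params, epoch = ep)
  }
  new("ActivityDecoder", params = best$params, config = cfg,
      categories = categories, history = hist)
}

#' Train the full Monte Carlo ensemble
#'
#' Trains one decoder per fold. The resulting list of models is the
#' ensemble used for full-video inference.
#'
#' @inheritParams trainFold
#' @param splits output of [makeSplits()].
#' @return List of [ActivityDecoder-class] objects, one per fold.
#' @export
trainEnsemble <- function(samples, splits, encoderCfg,
                          trainCfg = trainConfig(), categories = NULL,
                          verbose = FALSE) {
  if (is.null(categories)) {
    labs <- vapply(samples, category, character(1))
    categories <- sort(unique(labs[!is.na(labs)]))
  }
  lapply(splits, function(sp)
    trainFold(samples, sp, encoderCfg, trainCfg, categories = categories,
              verbose = verbose))
}

#' Per-sample test-set predictions of a fold
#'
#' @param samples list of labelled [VideoSample-class] objects.
#' @param split the fold's split (test videos are selected by video id).
#' @param model the fold's trained [ActivityDecoder-class].
#' @return data.frame with one row per test sample: \code{video_id},
#'   \code{label}, and one probability column per category.
#' @export
predictFold <- function(samples, split, model) {
  vids <- vapply(samples, videoId, character(1))
  testSet <- samples[vids %in% split$test]
  if (!length(testSet)) stop("split has no test samples")
  probs <- t(vapply(testSet, function(s) as.numeric(predictSample(s, model)),
                    numeric(length(model@categories))))
  colnames(probs) <- model@categories
  cbind(data.frame(video_id = vapply(testSet, videoId, character(1)),
                   label = vapply(testSet, category, character(1)),
                   stringsAsFactors = FALSE),
        as.data.frame(probs))
}
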