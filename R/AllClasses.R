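#' @import methods
NULL

#' Per-frame feature sequence for one modality of one clip
#'
#' Ordered per-frame feature vectors (one row per frame) for either the
#' appearance ("RGB") or motion (optical-flow) stream of a video clip,
#' together with the source frame indices, the recording rate and a
#' validity mask distinguishing real frames from zero padding.
#'
#' @slot modality either \code{"appearance"} or \code{"motion"}.
#' @slot vectors numeric matrix, T x D; row t is the feature vector of
#'   frame t. Padded rows (where \code{validMask} is \code{FALSE}) are
#'   all-zero.
#' @slot frameIndices integer vector of length T; strictly increasing,
#'   non-negative indices into the source video.
#' @slot fps frames per second of the source video.
#' @slot validMask logical vector of length T; \code{FALSE} marks padding.
#'
#' @seealso [FrameFeatureSequence()] for the user constructor.
#' @exportClass FrameFeatureSequence
setClass("FrameFeatureSequence",
  representation(
    modality = "character",
    vectors = "matrix",
    frameIndices = "integer",
    fps = "numeric",
    validMask = "logical"
  )
)

setValidity("FrameFeatureSequence", function(object) {
  msg <- character()
  if (!object@modality %in% c("appearance", "motion"))
    msg <- c(msg, "modality must be 'appearance' or 'motion'")
  Tn <- nrow(object@vectors)
  if (length(object@frameIndices) != Tn)
    msg <- c(msg, "length(frameIndices) must equal nrow(vectors)")
  if (length(object@validMask) != Tn)
    msg <- c(msg, "length(validMask) must equal nrow(vectors)")
  if (Tn > 1 && any(diff(object@frameIndices) <= 0))
    msg <- c(msg, "frameIndices must be strictly increasing")
  if (Tn > 0 && any(object@frameIndices < 0))
    msg <- c(msg, "frameIndices must be non-negative")
  if (length(object@fps) != 1 || !is.finite(object@fps) || object@fps <= 0)
    msg <- c(msg, "fps must be a single positive number")
  pad <- !object@validMask
  if (any(pad) && any(object@vectors[pad, , drop = FALSE] != 0))
    msg <- c(msg, "padded rows (validMask FALSE) must be all-zero")
  if (length(msg)) msg else TRUE
})

#' Construct a FrameFeatureSequence
#'
#' @param vectors T x D numeric matrix of per-frame features.
#' @param modality \code{"appearance"} or \code{"motion"}.
#' @param frameIndices integer indices of the frames in the source video;
#'   defaults to \code{0:(T-1)}.
#' @param fps frames per second of the source video.
#' @param validMask logical length-T mask; defaults to all \code{TRUE}.
#' @return A [FrameFeatureSequence-class] object.
#' @examples
#' fs <- FrameFeatureSequence(matrix(rnorm(20), 5, 4), "appearance", fps = 30)
#' nFrames(fs)
#' @export
FrameFeatureSequence <- function(vectors, modality = c("appearance", "motion"),
                                 frameIndices = NULL, fps = 30,
                                 validMask = NULL) {
  modality <- match.arg(modality)
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (is.null(frameIndices)) frameIndices <- seq_len(nrow(vectors)) - 1L
  if (is.null(validMask)) validMask <- rep(TRUE, nrow(vectors))
  new("FrameFeatureSequence",
    modality = modality, vectors = vectors,
    frameIndices = as.integer(frameIndices), fps = as.numeric(fps),
    validMask = as.logical(validMask)
  )
}

#' A labelled video clip with paired appearance and motion streams
#'
#' @slot videoId identifier of the source case video.
#' @slot startS,endS clip boundaries in seconds (half-open, end > start).
#' @slot category activity label, or \code{NA_character_} when unlabelled.
#' @slot appearance,motion the two [FrameFeatureSequence-class] streams.
#' @exportClass VideoSample
setClass("VideoSample",
  representation(
    videoId = "character",
    startS = "numeric",
    endS = "numeric",
    category = "character",
    appearance = "FrameFeatureSequence",
    motion = "FrameFeatureSequence"
  )
)

setValidity("VideoSample", function(object) {
  msg <- character()
  if (object@endS <= object@startS)
    msg <- c(msg, "endS must be greater than startS")
  if (object@appearance@modality != "appearance")
    msg <- c(msg, "appearance slot must hold an appearance-modality sequence")
  if (object@motion@modality != "motion")
    msg <- c(msg, "motion slot must hold a motion-modality sequence")
  if (ncol(object@appearance@vectors) != ncol(object@motion@vectors))
    msg <- c(msg, "appearance and motion feature dimensions differ")
  if (length(msg)) msg else TRUE
})

#' Construct a VideoSample
#'
#' @param videoId source video identifier.
#' @param startS,endS clip start and end in seconds.
#' @param appearance,motion [FrameFeatureSequence-class] objects for the
#'   two modality streams.
#' @param category activity label (or \code{NA} for unlabelled clips).
#' @return A [VideoSample-class] object.
#' @export
VideoSample <- function(videoId, startS, endS, appearance, motion,
                        category = NA_character_) {
  new("VideoSample",
    videoId = as.character(videoId), startS = as.numeric(startS),
    endS = as.numeric(endS), category = as.character(category),
    appearance = appearance, motion = motion
  )
}

#' Bank of learned category prototypes
#'
#' One E-dimensional prototype per category. Video embeddings are
#' classified by the softmax of their cosine similarities to the
#' prototypes.
#'
#' @slot prototypes C x E numeric matrix; row j is prototype p_j.
#' @slot categoryNames length-C character vector of category labels.
#' @exportClass PrototypeBank
setClass("PrototypeBank",
  representation(prototypes = "matrix", categoryNames = "character")
)

setValidity("PrototypeBank", function(object) {
  msg <- character()
  C <- nrow(object@prototypes)
  if (C < 2) msg <- c(msg, "at least two categories are required")
  if (length(object@categoryNames) != C)
    msg <- c(msg, "categoryNames length must match nrow(prototypes)")
  if (anyDuplicated(object@categoryNames))
    msg <- c(msg, "categoryNames must be unique")
  if (!all(is.finite(object@prototypes)))
    msg <- c(msg, "prototypes must be finite")
  if (any(rowSums(object@prototypes^2) == 0))
    msg <- c(msg, "prototypes must be nonzero")
  if (length(msg)) msg else TRUE
})

#' Construct a PrototypeBank
#'
#' @param prototypes C x E numeric matrix of prototypes (rows nonzero).
#' @param categoryNames length-C character vector of labels.
#' @return A [PrototypeBank-class] object.
#' @export
PrototypeBank <- function(prototypes, categoryNames) {
  prototypes <- as.matrix(prototypes)
  storage.mode(prototypes) <- "double"
  new("PrototypeBank",
    prototypes = prototypes,
    categoryNames = as.character(categoryNames)
  )
}

#' On-disk store of per-frame feature matrices
#'
#' A single-file container keyed by \code{video_id} and modality, holding
#' one T_total x D matrix per key plus an fps attribute, matching the
#' offline one-pass extraction workflow (features are extracted once and
#' reused for training and inference).
#'
#' @slot path path of the backing file.
#' @seealso [featureStore()], [storeFeatures()], [loadFeatures()]
#' @exportClass FeatureStore
setClass("FeatureStore", representation(path = "character"))

#' Trained activity decoder
#'
#' Holds the learned parameters of the two-stream temporal transformer
#' (shared across modalities), the projection head, the prototype bank
#' and the encoder configuration.
#'
#' @slot params list of learned arrays (cls embedding, positional
#'   embeddings, encoder layers, projection head, prototypes).
#' @slot config encoder configuration, see [encoderConfig()].
#' @slot categories category labels, in prototype order.
#' @slot history data.frame of per-epoch training/validation loss (may be
#'   empty for untrained models).
#' @exportClass ActivityDecoder
setClass("ActivityDecoder",
  representation(
    params = "list",
    config = "list",
    categories = "character",
    history = "data.frame"
  )
)

## ---- show methods -------------------------------------------------------

setMethod("show", "FrameFeatureSequence", function(object) {
  cat(sprintf(
    "FrameFeatureSequence [%s]: %d frames (%d valid) x %d dims, %.4g fps\n",
    object@modality, nrow(object@vectors), sum(object@validMask),
    ncol(object@vectors), object@fps
  ))
})

setMethod("show", "VideoSample", function(object) {
  cat(sprintf(
    "VideoSample '%s' [%.2f, %.2f) s, category: %s\n",
    object@videoId, object@startS, object@endS,
    ifelse(is.na(object@category), "<unlabelled>", object@category)
  ))
  show(object@appearance)
  show(object@motion)
})

setMethod("show", "PrototypeBank", function(object) {
  cat(sprintf(
    "PrototypeBank: %d categories x %d dims (%s)\n",
    nrow(object@prototypes), ncol(object@prototypes),
    paste(object@categoryNames, collapse = ", ")
  ))
})

setMethod("show", "FeatureStore", function(object) {
  keys <- tryCatch(listFeatures(object), error = function(e) NULL)
  cat(sprintf("FeatureStore at '%s': %d entries\n", object@path,
              if (is.null(keys)) 0L else nrow(keys)))
})

setMethod("show", "ActivityDecoder", function(object) {
  cat(sprintf(
    "ActivityDecoder: D=%d, E=%d, %d encoder layer(s), %d head(s), %d categories\n",
    object@config$D, object@config$E, object@config$n_layers,
    object@config$n_heads, length(object@categories)
  ))
  if (nrow(object@history)) {
    cat(sprintf("  trained %d epochs; best validation loss %.4f\n",
                max(object@history$epoch), min(object@history$val_loss)))
  }
})

## ---- accessors ----------------------------------------------------------

#' Accessors for the core classes
#'
#' \code{nFrames} returns the number of (possibly padded) frames of a
#' sequence; \code{featureMatrix} its T x D matrix; \code{validMask} its
#' padding mask; \code{modality} its stream name. \code{videoId},
#' \code{category}, \code{appearanceSeq} and \code{motionSeq} access the
#' components of a [VideoSample-class]. \code{prototypeMatrix} and
#' \code{categoryNames} access a [PrototypeBank-class];
#' \code{prototypeBank} extracts the bank of an
#' [ActivityDecoder-class].
#'
#' @param x the object.
#' @return The accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
nFrames <- function(x) nrow(x@vectors)

#' @rdname accessors
#' @export
featureMatrix <- function(x) x@vectors

#' @rdname accessors
#' @export
validMask <- function(x) x@validMask

#' @rdname accessors
#' @export
modality <- function(x) x@modality

#' @rdname accessors
#' @export
videoId <- function(x) x@videoId

#' @rdname accessors
#' @export
category <- function(x) x@category

#' @rdname accessors
#' @export
appearanceSeq <- function(x) x@appearance

#' @rdname accessors
#' @export
motionSeq <- function(x) x@motion

#' @rdname accessors
#' @export
prototypeMatrix <- function(x) x@prototypes

#' @rdname accessors
#' @export
categoryNames <- function(x) x@categoryNames

#' @rdname accessors
#' @export
prototypeBank <- function(x) {
  stopifnot(is(x, "ActivityDecoder"))
  PrototypeBank(x@params$proto, x@categories)
}
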