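#' Task-specific frame sampling
#'
#' Selects which frames of a clip are presented to the temporal encoder.
#' Gesture classification uses ten equally spaced frames (spacing
#' \code{floor((n-1)/9)}, first frame 0), so a 3-s clip at 30 fps (90
#' frames) yields indices 0, 9, 18, ..., 81. Subphase recognition and
#' skill assessment use every tenth frame: 0, 10, 20, ... Clips with
#' fewer than ten frames under the gesture rule fall back to all frames
#' (with a message).
#'
#' @param task \code{"gesture"} or \code{"subphase_or_skill"}.
#' @param nTotalFrames number of frames in the clip (>= 1).
#' @param offset start-frame offset in frames (used by test-time
#'   augmentation); indices exceeding the clip are dropped.
#' @return Sorted unique integer frame indices (0-based).
#' @examples
#' sampleFrameIndices("gesture", 90)           # 0, 9, 18, ..., 81
#' sampleFrameIndices("subphase_or_skill", 90) # 0, 10, 20, ..., 80
#' @export
sampleFrameIndices <- function(task = c("gesture", "subphase_or_skill"),
                               nTotalFrames, offset = 0L) {
  task <- match.arg(task)
  if (!.isCount(nTotalFrames))
    stop("nTotalFrames must be a positive integer")
  n <- as.integer(nTotalFrames)
  offset <- as.integer(offset)
  if (offset < 0) stop("offset must be non-negative")
  if (task == "gesture") {
    if (n < 10L) {
      message(sprintf(
        "clip has %d < 10 frames; falling back to all frames for gesture sampling", n))
      idx <- seq_len(n) - 1L + offset
    } else {
      spacing <- (n - 1L) %/% 9L
      idx <- offset + spacing * (0:9)
    }
  } else {
    idx <- seq.int(offset, by = 10L, length.out = max(0L, ((n - 1L - offset) %/% 10L) + 1L))
  }
  idx <- idx[idx < n]
  sort(unique(as.integer(idx)))
}

#' Pair motion (optical-flow) frames with appearance frames
#'
#' Optical-flow maps are computed from pairs of images a fixed time apart
#' (default 0.5 s); this returns, for each retrieved appearance frame,
#' the frame pair whose flow map overlaps it in time. The pair
#' separation is \code{round(fps * flowDt)} frames.
#'
#' @param rgbIndices integer indices of the retrieved appearance frames.
#' @param fps frames per second (> 0).
#' @param flowDt temporal separation of the image pair in seconds (> 0).
#' @param nTotalFrames optional clip length in frames; pairs whose second
#'   frame falls outside the clip are dropped.
#' @return A two-column integer matrix with columns \code{i} and
#'   \code{j}; each row is one (i, j) frame pair with
#'   \code{j - i == round(fps * flowDt)}. A clip shorter than
#'   \code{flowDt} yields zero rows with a warning.
#' @examples
#' pairMotionFrames(c(0, 9, 18), fps = 30, flowDt = 0.5)
#' @export
pairMotionFrames <- function(rgbIndices, fps, flowDt = 0.5,
                             nTotalFrames = NULL) {
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0)
    stop("fps must be a single positive number")
  if (!is.numeric(flowDt) || length(flowDt) != 1 || flowDt <= 0)
    stop("flowDt must be a single positive number")
  sep <- as.integer(round(fps * flowDt))
  i <- as.integer(rgbIndices)
  j <- i + sep
  if (!is.null(nTotalFrames)) {
    keep <- j < nTotalFrames
    if (!any(keep)) {
      warning("clip is shorter than flowDt; no motion frame pairs available")
      return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
    }
    i <- i[keep]; j <- j[keep]
  }
  cbind(i = i, j = j)
}

#' Timestamps of frames within a clip
#'
#' Frame k of a clip starting at \code{startS} seconds and recorded at
#' \code{fps} frames per second occurs at \code{startS + k / fps}.
#'
#' @param frameIndices integer frame indices (0-based).
#' @param startS clip start time in seconds.
#' @param fps frames per second.
#' @return Numeric timestamps in seconds.
#' @export
frameTimestamps <- function(frameIndices, startS = 0, fps = 30) {
  startS + as.numeric(frameIndices) / fps
}

## ---- feature store ------------------------------------------------------

#' Open (or create) a feature store
#'
#' The store is a single file holding one T_total x D matrix per
#' \code{video_id}/modality key plus a per-matrix fps attribute, written
#' once after offline feature extraction and reused for training and
#' inference. Roundtrips are bit-exact.
#'
#' @param path path of the backing file; created on first store.
#' @return A [FeatureStore-class] handle.
#' @export
featureStore <- function(path) {
  new("FeatureStore", path = as.character(path))
}

.readStore <- function(store) {
  if (!file.exists(store@path)) return(list())
  readRDS(store@path)
}

#' Store a feature matrix
#'
#' @param store a [FeatureStore-class] handle.
#' @param videoId video identifier.
#' @param modality \code{"appearance"} or \code{"motion"}.
#' @param matrix T_total x D numeric matrix of per-frame features.
#' @param fps frames per second recorded alongside the matrix.
#' @return The store handle, invisibly.
#' @export
storeFeatures <- function(store, videoId, modality = c("appearance", "motion"),
                          matrix, fps = 30) {
  modality <- match.arg(modality)
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  attr(m, "fps") <- as.numeric(fps)
  db <- .readStore(store)
  vid <- as.character(videoId)
  if (is.null(db[[vid]])) db[[vid]] <- list()
  db[[vid]][[modality]] <- m
  saveRDS(db, store@path)
  invisible(store)
}

#' Load a feature matrix
#'
#' @inheritParams storeFeatures
#' @return The stored matrix, with its \code{fps} attribute.
#' @export
loadFeatures <- function(store, videoId, modality = c("appearance", "motion")) {
  modality <- match.arg(modality)
  db <- .readStore(store)
  vid <- as.character(videoId)
  if (is.null(db[[vid]]) || is.null(db[[vid]][[modality]]))
    stop(sprintf("no features stored for video '%s', modality '%s'", vid, modality))
  db[[vid]][[modality]]
}

#' List the contents of a feature store
#'
#' @param store a [FeatureStore-class] handle.
#' @return data.frame with columns \code{video_id}, \code{modality},
#'   \code{n_frames}, \code{dim}, \code{fps}.
#' @export
listFeatures <- function(store) {
  db <- .readStore(store)
  rows <- list()
  for (vid in names(db)) {
    for (mod in names(db[[vid]])) {
      m <- db[[vid]][[mod]]
      rows[[length(rows) + 1L]] <- data.frame(
        video_id = vid, modality = mod, n_frames = nrow(m),
        dim = ncol(m), fps = attr(m, "fps"), stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(video_id = character(), modality = character(),
                      n_frames = integer(), dim = integer(), fps = numeric()))
  }
  do.call(rbind, rows)
}

## ---- clip annotation tables ---------------------------------------------

#' Read or write clip annotation tables
#'
#' Annotations are TSV files with columns \code{video_id},
#' \code{start_s}, \code{end_s}, \code{category} (one row per labelled
#' clip; \code{category} may be empty for unlabelled clips).
#'
#' @param path TSV file path.
#' @return \code{readClipAnnotations} returns a data.frame with the four
#'   columns above.
#' @export
readClipAnnotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("video_id", "start_s", "end_s", "category")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("annotation table lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  if (any(df$end_s <= df$start_s))
    stop("annotation table contains clips with end_s <= start_s")
  df[need]
}

#' @rdname readClipAnnotations
#' @param annotations data.frame with the four annotation columns.
#' @export
writeClipAnnotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Cut a labelled clip out of a stored full-video feature stream
#'
#' Retrieves the task-appropriate frames between \code{startS} and
#' \code{endS} from both modality streams of \code{videoId} in the store
#' and assembles a [VideoSample-class].
#'
#' @param store a [FeatureStore-class] handle.
#' @param videoId video identifier.
#' @param startS,endS clip boundaries in seconds (half-open).
#' @param task frame-sampling rule, see [sampleFrameIndices()].
#' @param category optional label.
#' @param offset start-frame offset (test-time augmentation).
#' @return A [VideoSample-class].
#' @export
extractClip <- function(store, videoId, startS, endS,
                        task = c("gesture", "subphase_or_skill"),
                        category = NA_character_, offset = 0L) {
  task <- match.arg(task)
  app <- loadFeatures(store, videoId, "appearance")
  mot <- loadFeatures(store, videoId, "motion")
  fps <- attr(app, "fps")
  f0 <- as.integer(floor(startS * fps))
  f1 <- min(as.integer(ceiling(endS * fps)), nrow(app))
  nClip <- f1 - f0
  if (nClip < 1) stop("clip contains no frames")
  rel <- sampleFrameIndices(task, nClip, offset = offset)
  absIdx <- f0 + rel
  appSeq <- FrameFeatureSequence(app[absIdx + 1L, , drop = FALSE], "appearance",
                                 frameIndices = absIdx, fps = fps)
  motSeq <- FrameFeatureSequence(mot[pmin(absIdx, nrow(mot) - 1L) + 1L, , drop = FALSE],
                                 "motion", frameIndices = absIdx, fps = fps)
  VideoSample(videoId, startS, endS, appSeq, motSeq, category = category)
}
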