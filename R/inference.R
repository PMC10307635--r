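#' Inference configuration for full-video decoding
#'
#' @param regime \code{"subphase"} (10-s windows with 5-s overlap plus
#'   5-s non-overlapping windows) or \code{"gesture"} (1-s
#'   non-overlapping windows).
#' @param tta_offsets start-frame offsets of the test-time augmentation
#'   inputs (default \code{c(0, 3, 6)}).
#' @param S_thresh entropy threshold in nats; bagged predictions with
#'   entropy strictly above it are abstained from. Default 1.74 for the
#'   gesture regime; for the subphase regime the default is
#'   \code{0.95 * log(nCategories)} (set at decode time), a package
#'   default rather than a published value.
#' @param chain_gap chaining gap in seconds: same-category predictions
#'   closer than this merge into one event. Default 3 (subphase) or 2
#'   (gesture).
#' @param n_folds expected ensemble size (informational; the decoder
#'   uses however many checkpoints it is given).
#' @return A validated list of class \code{"inferenceConfig"}.
#' @export
inferenceConfig <- function(regime = c("subphase", "gesture"),
                            tta_offsets = c(0L, 3L, 6L), S_thresh = NULL,
                            chain_gap = NULL, n_folds = 10L) {
  regime <- match.arg(regime)
  tta_offsets <- as.integer(tta_offsets)
  if (anyDuplicated(tta_offsets) || any(tta_offsets < 0))
    stop("tta_offsets must be distinct and non-negative")
  if (is.null(chain_gap)) chain_gap <- if (regime == "subphase") 3 else 2
  if (chain_gap < 0) stop("chain_gap must be >= 0")
  if (is.null(S_thresh) && regime == "gesture") S_thresh <- 1.74
  if (!is.null(S_thresh) && S_thresh <= 0)
    stop("S_thresh must be positive (in (0, log(C)])")
  cfg <- list(regime = regime, tta_offsets = tta_offsets,
              S_thresh = S_thresh, chain_gap = as.numeric(chain_gap),
              n_folds = as.integer(n_folds))
  class(cfg) <- "inferenceConfig"
  cfg
}

#' Curate inference windows over an unannotated video
#'
#' Subphase regime: the union of 10-s windows stepping by 5 s
#' (approach 1, capturing boundary activity through the overlap) and 5-s
#' windows stepping by 5 s (approach 2, capturing brief subphases).
#' Gesture regime: 1-s non-overlapping windows. Trailing partial windows
#' are dropped.
#'
#' @param durationS video duration in seconds (> 0).
#' @param regime \code{"subphase"} or \code{"gesture"}.
#' @return data.frame with columns \code{start_s}, \code{end_s},
#'   \code{approach}; zero rows (with a warning) when the video is
#'   shorter than the smallest window.
#' @export
curateWindows <- function(durationS, regime = c("subphase", "gesture")) {
  regime <- match.arg(regime)
  if (durationS <= 0) stop("durationS must be positive")
  win <- function(len, step) {
    if (durationS < len)
      return(data.frame(start_s = numeric(), end_s = numeric()))
    starts <- seq(0, durationS - len, by = step)
    starts <- starts[starts + len <= durationS + 1e-9]
    data.frame(start_s = starts, end_s = starts + len)
  }
  out <- if (regime == "subphase") {
    a1 <- win(10, 5); a2 <- win(5, 5)
    rbind(
      if (nrow(a1)) cbind(a1, approach = 1L) else NULL,
      if (nrow(a2)) cbind(a2, approach = 2L) else NULL
    )
  } else {
    a <- win(1, 1)
    if (nrow(a)) cbind(a, approach = 1L) else NULL
  }
  if (is.null(out) || !nrow(out)) {
    warning("video shorter than the smallest inference window; no windows curated")
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      approach = integer()))
  }
  rownames(out) <- NULL
  out
}

#' Test-time augmentation frame-index sets for a window
#'
#' Returns one frame-index set per TTA offset: the regime's sampling
#' rule applied with the start frame shifted by the offset (indices
#' beyond the clip are dropped).
#'
#' @param nFrames number of frames in the window.
#' @param regime \code{"subphase"} or \code{"gesture"} (selects the
#'   sampling rule of [sampleFrameIndices()]).
#' @param offsets integer start-frame offsets (default \code{c(0,3,6)}).
#' @return List of integer index vectors, one per offset.
#' @export
ttaFrameIndices <- function(nFrames, regime = c("subphase", "gesture"),
                            offsets = c(0L, 3L, 6L)) {
  regime <- match.arg(regime)
  task <- if (regime == "gesture") "gesture" else "subphase_or_skill"
  lapply(as.integer(offsets), function(k)
    suppressMessages(sampleFrameIndices(task, nFrames, offset = k)))
}

#' Average (bag) the probabilistic outputs for one timespan
#'
#' Arithmetic mean of the probability masses accumulated for a timespan
#' across window approaches, ensemble folds and TTA variants.
#'
#' @param cells list of ensemble cells: each a list with \code{probs}
#'   (probability vector) and \code{timespan} (\code{c(start, end)}).
#' @return The averaged probability mass (sums to 1).
#' @export
bagCells <- function(cells) {
  if (!length(cells)) stop("at least one cell is required")
  spans <- vapply(cells, function(cl) cl$timespan, numeric(2))
  if (any(abs(spans - spans[, 1]) > 1e-9))
    stop("cells with mixed timespans cannot be bagged")
  P <- vapply(cells, function(cl) as.numeric(cl$probs),
              numeric(length(cells[[1]]$probs)))
  rowMeans(rbind(P))
}

#' Entropy-based abstention
#'
#' Computes the natural-log entropy of a bagged probability mass and
#' abstains when it strictly exceeds the threshold (high entropy = high
#' uncertainty, e.g. out-of-distribution or ambiguous content);
#' otherwise keeps the argmax label.
#'
#' @param probs probability mass over categories (named, or labels given
#'   via \code{categories}).
#' @param S_thresh entropy threshold in nats.
#' @param categories optional category labels.
#' @return List with \code{keep} (logical), \code{entropy}, and
#'   \code{label} (\code{NA} when abstaining).
#' @export
entropyAbstain <- function(probs, S_thresh, categories = names(probs)) {
  S <- .entropyNat(probs)
  keep <- S <= S_thresh
  label <- if (keep) {
    if (is.null(categories)) which.max(probs) else categories[which.max(probs)]
  } else NA
  list(keep = keep, entropy = S, label = label)
}

#' Chain kept predictions into events
#'
#' Merges same-category predictions into a single event when the gap
#' between them (next start minus previous end) is strictly less than
#' \code{chainGap} seconds; overlapping same-category predictions are
#' unioned first. Different categories never merge. Idempotent. E.g., a
#' retraction predicted at 10-11 s, 11-12 s and 15-16 s with a 2-s gap
#' yields two events: 10-12 s and 15-16 s.
#'
#' @param predictions data.frame with columns \code{start_s},
#'   \code{end_s}, \code{category} (time-sorted or not; sorted
#'   internally).
#' @param chainGap merging gap in seconds (>= 0).
#' @return data.frame of events: \code{category}, \code{start_s},
#'   \code{end_s}; per-category events are disjoint and time-sorted.
#' @export
chainEvents <- function(predictions, chainGap) {
  if (chainGap < 0) stop("chainGap must be >= 0")
  if (!nrow(predictions)) {
    return(data.frame(category = character(), start_s = numeric(),
                      end_s = numeric()))
  }
  out <- lapply(split(predictions, predictions$category), function(df) {
    df <- df[order(df$start_s, df$end_s), , drop = FALSE]
    starts <- df$start_s[1]; ends <- df$end_s[1]
    for (i in seq_len(nrow(df))[-1]) {
      k <- length(ends)
      # union overlaps, then merge if the gap is strictly below chainGap
      if (df$start_s[i] - ends[k] < chainGap) {
        ends[k] <- max(ends[k], df$end_s[i])
      } else {
        starts <- c(starts, df$start_s[i])
        ends <- c(ends, df$end_s[i])
      }
    }
    data.frame(category = df$category[1], start_s = starts, end_s = ends,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$start_s, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Activity profile and low-skill ratio of a case
#'
#' Builds the per-category timeline of decoded events and, when a
#' binary skill label per event is supplied, the ratio of low-skill
#' events in the case.
#'
#' @param events data.frame of events ([chainEvents()] output).
#' @param skillLabels optional per-event labels; entries equal to
#'   \code{lowLabel} count as low skill.
#' @param lowLabel the label counted as low skill (default
#'   \code{"low"}).
#' @return List with \code{timeline} (events ordered by category and
#'   time) and \code{low_skill_ratio} (\code{NULL} when there are no
#'   events or no labels).
#' @export
activityProfile <- function(events, skillLabels = NULL, lowLabel = "low") {
  timeline <- events[order(events$category, events$start_s), , drop = FALSE]
  rownames(timeline) <- NULL
  ratio <- NULL
  if (!is.null(skillLabels)) {
    if (length(skillLabels) != nrow(events))
      stop("one skill label per event is required")
    ratio <- if (!nrow(events)) NULL else mean(skillLabels == lowLabel)
  }
  list(timeline = timeline, low_skill_ratio = ratio)
}

# Map a window to the 10-s timespans it feeds. Timespans live on the
# 5-s grid; an approach-1 window feeds the timespan sharing its start,
# an approach-2 window feeds the (up to two) 10-s timespans containing
# it. Gesture windows are their own timespans.
.windowTimespans <- function(startS, endS, approach, regime, durationS) {
  if (regime == "gesture") return(list(c(startS, endS)))
  if (approach == 1L) return(list(c(startS, endS)))
  spans <- list(c(startS - 5, startS + 5), c(startS, startS + 10))
  Filter(function(ts) ts[1] >= -1e-9 && ts[2] <= durationS + 1e-9, spans)
}

#' Decode an entire unannotated video
#'
#' Runs the full inference stack: curates windows, builds the TTA
#' inputs for each window, scores each with every ensemble model, pools
#' the probabilistic outputs per timespan (bagging), abstains from
#' high-entropy timespans and chains the kept predictions into events.
#'
#' @param appearance,motion T_total x D feature matrices of the full
#'   video (motion aligned frame-by-frame with appearance).
#' @param fps frames per second of the feature streams.
#' @param models list of trained [ActivityDecoder-class] objects (the
#'   cross-validation ensemble).
#' @param config an [inferenceConfig()].
#' @param ignoreCategories categories whose kept predictions are
#'   discarded before chaining (e.g. an explicit background/idle class
#'   in a closed-world decoder); they never become events.
#' @return List with \code{events} (chained events data.frame),
#'   \code{kept} (kept per-timespan predictions), \code{bagged}
#'   (per-timespan averaged masses with entropy) and \code{n_cells}
#'   (ensemble cells accumulated per timespan).
#' @export
decodeVideo <- function(appearance, motion, fps, models, config,
                        ignoreCategories = character()) {
  stopifnot(inherits(config, "inferenceConfig"), length(models) >= 1)
  categories <- models[[1]]@categories
  for (m in models) {
    if (!identical(m@categories, categories))
      stop("all ensemble models must share the same categories")
  }
  C <- length(categories)
  Sthr <- config$S_thresh
  if (is.null(Sthr)) Sthr <- 0.95 * log(C)
  durationS <- nrow(appearance) / fps
  windows <- curateWindows(durationS, config$regime)
  if (!nrow(windows)) {
    empty <- data.frame(category = character(), start_s = numeric(),
                        end_s = numeric())
    return(list(events = empty, kept = empty, bagged = NULL,
                n_cells = integer()))
  }
  task <- if (config$regime == "gesture") "gesture" else "subphase_or_skill"
  cells <- list()
  for (w in seq_len(nrow(windows))) {
    f0 <- as.integer(round(windows$start_s[w] * fps))
    nWin <- as.integer(round((windows$end_s[w] - windows$start_s[w]) * fps))
    nWin <- min(nWin, nrow(appearance) - f0)
    if (nWin < 1) next
    ttaSets <- ttaFrameIndices(nWin, config$regime, config$tta_offsets)
    spans <- .windowTimespans(windows$start_s[w], windows$end_s[w],
                              windows$approach[w], config$regime, durationS)
    for (k in seq_along(ttaSets)) {
      idx <- ttaSets[[k]]
      if (!length(idx)) next
      rows <- f0 + idx + 1L
      appSeq <- FrameFeatureSequence(appearance[rows, , drop = FALSE],
                                     "appearance", frameIndices = f0 + idx,
                                     fps = fps)
      motSeq <- FrameFeatureSequence(motion[pmin(rows, nrow(motion)), , drop = FALSE],
                                     "motion", frameIndices = f0 + idx,
                                     fps = fps)
      sample <- VideoSample("inference", windows$start_s[w], windows$end_s[w],
                            appSeq, motSeq)
      for (f in seq_along(models)) {
        probs <- predictSample(sample, models[[f]])
        for (ts in spans) {
          key <- sprintf("%.3f_%.3f", ts[1], ts[2])
          cells[[key]] <- c(cells[[key]], list(list(
            probs = as.numeric(probs), timespan = ts,
            provenance = c(approach = windows$approach[w], fold = f, tta = k)
          )))
        }
      }
    }
  }
  if (!length(cells)) {
    empty <- data.frame(category = character(), start_s = numeric(),
                        end_s = numeric())
    return(list(events = empty, kept = empty, bagged = NULL,
                n_cells = integer()))
  }
  keys <- names(cells)
  starts <- as.numeric(vapply(strsplit(keys, "_"), `[`, character(1), 1))
  ord <- order(starts)
  bagged <- do.call(rbind, lapply(keys[ord], function(key) {
    sbar <- bagCells(cells[[key]])
    ts <- cells[[key]][[1]]$timespan
    ab <- entropyAbstain(sbar, Sthr, categories)
    data.frame(start_s = ts[1], end_s = ts[2], entropy = ab$entropy,
               keep = ab$keep,
               label = ifelse(ab$keep, ab$label, NA_character_),
               t(sbar), stringsAsFactors = FALSE)
  }))
  names(bagged)[6:(5 + C)] <- categories
  kept <- bagged[bagged$keep, c("start_s", "end_s", "label")]
  names(kept)[3] <- "category"
  events <- chainEvents(kept[!kept$category %in% ignoreCategories, ,
                             drop = FALSE], config$chain_gap)
  list(events = events, kept = kept, bagged = bagged,
       n_cells = vapply(cells[keys[ord]], length, integer(1)))
}

#' Write decoded events to TSV
#'
#' @param events events data.frame ([chainEvents()] output).
#' @param videoId video identifier recorded in the first column.
#' @param path TSV path.
#' @export
writeEvents <- function(events, videoId, path) {
  out <- cbind(video_id = rep(videoId, nrow(events)), events)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
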