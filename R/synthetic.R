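#' Synthetic feature-stream configuration
#'
#' Configures the generator of class-conditional, temporally smooth,
#' modality-correlated feature streams used to exercise every module
#' without real surgical video. Each category has a fixed unit mean
#' direction in feature space; appearance frames are that direction
#' scaled by \code{snr} plus AR(1) noise of unit stationary variance,
#' and motion frames are \code{modality_correlation} times the
#' appearance frame plus independent noise. The defaults are desk-scale
#' (D = 32) so that tests run quickly; pass \code{D = 384} for
#' full-size streams.
#'
#' @param categories character vector of category labels (>= 2).
#' @param D feature dimension (default 32).
#' @param fps frames per second (default 30).
#' @param snr separation of the class means in noise-standard-deviation
#'   units (>= 0; 0 means no class signal).
#' @param temporal_smoothness AR(1) coefficient of the frame noise in
#'   [0, 1) (default 0.8, emulating the smoothness of video).
#' @param modality_correlation coupling of the motion stream to the
#'   appearance stream in [0, 1] (default 0.7).
#' @param duration_range per-category clip duration range in seconds;
#'   either a length-2 vector shared by all categories or a named list.
#' @param gap_range inter-event background gap range in seconds (for
#'   timelines).
#' @param motif ordered character vector of categories planted
#'   repeatedly in timelines (default the non-background categories,
#'   emulating the recurring hook-clip-cold-cut dissection pattern).
#' @param background optional name of a category with no class signal
#'   (zero mean direction): clips of it are pure noise, statistically
#'   identical to the inter-event background of timelines. Training with
#'   such a class gives a closed-world decoder that can label idle
#'   content explicitly.
#' @param seed base seed; category mean directions are derived from it.
#' @return A validated list of class \code{"syntheticConfig"}.
#' @export
syntheticConfig <- function(categories = c("hook", "clip", "cold_cut"),
                            D = 32L, fps = 30, snr = 5,
                            temporal_smoothness = 0.8,
                            modality_correlation = 0.7,
                            duration_range = c(1, 5), gap_range = c(3, 8),
                            motif = NULL, background = NULL, seed = 1L) {
  categories <- as.character(categories)
  if (length(categories) < 2) stop("at least two categories are required")
  if (!is.null(background) && !background %in% categories)
    stop("the background category must be listed in categories")
  if (snr < 0) stop("snr must be >= 0")
  if (temporal_smoothness < 0 || temporal_smoothness >= 1)
    stop("temporal_smoothness must be in [0, 1)")
  if (modality_correlation < 0 || modality_correlation > 1)
    stop("modality_correlation must be in [0, 1]")
  if (is.null(motif)) motif <- setdiff(categories, background)
  if (!all(motif %in% categories)) stop("motif uses unknown categories")
  if (!is.null(background) && background %in% motif)
    stop("the background category cannot be part of the motif")
  if (!is.list(duration_range))
    duration_range <- stats::setNames(
      rep(list(as.numeric(duration_range)), length(categories)), categories)
  if (any(vapply(duration_range, function(r) any(r <= 0), logical(1))))
    stop("durations must be positive")
  cfg <- list(categories = categories, D = as.integer(D),
              fps = as.numeric(fps), snr = as.numeric(snr),
              temporal_smoothness = as.numeric(temporal_smoothness),
              modality_correlation = as.numeric(modality_correlation),
              duration_range = duration_range,
              gap_range = as.numeric(gap_range), motif = motif,
              background = background, seed = as.integer(seed))
  class(cfg) <- "syntheticConfig"
  cfg
}

# Fixed unit mean direction per category, a pure function of the config
# seed (independent of the clip RNG stream).
.classMeans <- function(config) {
  rs <- .saveRNG()
  on.exit(.restoreRNG(rs))
  set.seed(.deriveSeed(config$seed, 7919L))
  M <- matrix(stats::rnorm(length(config$categories) * config$D),
              length(config$categories), config$D)
  M <- M / sqrt(rowSums(M^2))
  if (!is.null(config$background))
    M[match(config$background, config$categories), ] <- 0
  M
}

.saveRNG <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restoreRNG <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

# AR(1) noise matrix with unit stationary variance: n frames x D dims.
.ar1Noise <- function(n, D, phi) {
  sdInnov <- sqrt(1 - phi^2)
  X <- matrix(0, n, D)
  X[1, ] <- stats::rnorm(D)
  if (n > 1) {
    for (t in 2:n) X[t, ] <- phi * X[t - 1, ] + sdInnov * stats::rnorm(D)
  }
  X
}

# Frame block for one event (or background when category is NA).
.frameBlock <- function(n, category, config, means) {
  phi <- config$temporal_smoothness
  app <- .ar1Noise(n, config$D, phi)
  if (!is.na(category)) {
    mu <- means[match(category, config$categories), ]
    app <- app + matrix(mu * config$snr, n, config$D, byrow = TRUE)
  }
  rho <- config$modality_correlation
  mot <- rho * app + sqrt(max(0, 1 - rho^2)) * .ar1Noise(n, config$D, phi)
  list(appearance = app, motion = mot)
}

#' Generate one labelled synthetic clip
#'
#' @param category category label of the clip.
#' @param config a [syntheticConfig()].
#' @param videoId video identifier to attach (default \code{"sim"}).
#' @param seed RNG seed for this clip; same seed, same clip.
#' @param startS clip start time in seconds.
#' @return A labelled [VideoSample-class] with paired appearance and
#'   motion streams.
#' @export
genClip <- function(category, config, videoId = "sim", seed = 1L,
                    startS = 0) {
  stopifnot(inherits(config, "syntheticConfig"))
  if (!category %in% config$categories) stop("unknown category")
  means <- .classMeans(config)
  set.seed(seed)
  dr <- config$duration_range[[category]]
  dur <- stats::runif(1, dr[1], dr[2])
  n <- max(2L, as.integer(round(dur * config$fps)))
  blk <- .frameBlock(n, category, config, means)
  idx <- as.integer(round(startS * config$fps)) + seq_len(n) - 1L
  VideoSample(videoId, startS, startS + n / config$fps,
    FrameFeatureSequence(blk$appearance, "appearance", frameIndices = idx,
                         fps = config$fps),
    FrameFeatureSequence(blk$motion, "motion", frameIndices = idx,
                         fps = config$fps),
    category = category)
}

#' Generate a labelled clip corpus
#'
#' Generates \code{clipsPerVideo} clips for each of \code{nVideos}
#' synthetic videos, cycling through the categories, with the
#' task-specific frame sampling applied (so clips look exactly like
#' training inputs).
#'
#' @param config a [syntheticConfig()].
#' @param nVideos number of synthetic videos.
#' @param clipsPerVideo clips per video.
#' @param task frame-sampling rule, see [sampleFrameIndices()].
#' @param seed base seed.
#' @return List with \code{samples} (list of [VideoSample-class]) and
#'   \code{annotations} (data.frame in the clip-annotation format).
#' @export
genClipSet <- function(config, nVideos = 40L, clipsPerVideo = 10L,
                       task = c("gesture", "subphase_or_skill"), seed = 1L) {
  task <- match.arg(task)
  cats <- config$categories
  samples <- list()
  ann <- list()
  k <- 0L
  for (v in seq_len(nVideos)) {
    vid <- sprintf("video%03d", v)
    t0 <- 0
    for (cidx in seq_len(clipsPerVideo)) {
      k <- k + 1L
      cl <- cats[((k - 1L) %% length(cats)) + 1L]
      full <- genClip(cl, config, videoId = vid,
                      seed = .deriveSeed(seed, k), startS = t0)
      samples[[k]] <- .subsampleClip(full, task)
      ann[[k]] <- data.frame(video_id = vid, start_s = full@startS,
                             end_s = full@endS, category = cl,
                             stringsAsFactors = FALSE)
      t0 <- full@endS + 1
    }
  }
  list(samples = samples, annotations = do.call(rbind, ann))
}

# Apply the task frame-sampling rule to a dense clip.
.subsampleClip <- function(sample, task) {
  n <- nFrames(sample@appearance)
  idx <- suppressMessages(sampleFrameIndices(task, n)) + 1L
  take <- function(fs) {
    FrameFeatureSequence(fs@vectors[idx, , drop = FALSE], fs@modality,
                         frameIndices = fs@frameIndices[idx], fps = fs@fps)
  }
  new("VideoSample", videoId = sample@videoId, startS = sample@startS,
      endS = sample@endS, category = sample@category,
      appearance = take(sample@appearance), motion = take(sample@motion))
}

#' Generate a full-video timeline with planted events
#'
#' Walks the configured motif repeatedly until the requested duration is
#' filled: for each motif step an event of that category is planted
#' (duration drawn from its range) followed by a background gap of
#' zero-mean noise. Returns the dense two-modality feature stream plus
#' the ground-truth event intervals, directly usable by
#' [decodeVideo()] and [segmentalF1()].
#'
#' @param durationS total timeline duration in seconds.
#' @param config a [syntheticConfig()].
#' @param seed RNG seed.
#' @return List with \code{appearance}, \code{motion} (T_total x D
#'   matrices), \code{fps} and \code{truth} (data.frame of events:
#'   \code{category}, \code{start_s}, \code{end_s}).
#' @export
genTimeline <- function(durationS, config, seed = 1L) {
  stopifnot(inherits(config, "syntheticConfig"))
  means <- .classMeans(config)
  set.seed(seed)
  fps <- config$fps
  nTotal <- as.integer(round(durationS * fps))
  app <- matrix(0, nTotal, config$D)
  mot <- matrix(0, nTotal, config$D)
  truth <- list()
  # leading gap, then motif events separated by background gaps
  t <- stats::runif(1, config$gap_range[1], config$gap_range[2])
  stepIdx <- 0L
  repeat {
    cl <- config$motif[(stepIdx %% length(config$motif)) + 1L]
    dr <- config$duration_range[[cl]]
    dur <- stats::runif(1, dr[1], dr[2])
    if (t + dur > durationS) break
    f0 <- as.integer(round(t * fps))
    n <- as.integer(round(dur * fps))
    n <- min(n, nTotal - f0)
    if (n < 1) break
    blk <- .frameBlock(n, cl, config, means)
    app[f0 + seq_len(n), ] <- blk$appearance
    mot[f0 + seq_len(n), ] <- blk$motion
    truth[[length(truth) + 1L]] <- data.frame(
      category = cl, start_s = f0 / fps, end_s = (f0 + n) / fps,
      stringsAsFactors = FALSE)
    t <- (f0 + n) / fps + stats::runif(1, config$gap_range[1], config$gap_range[2])
    stepIdx <- stepIdx + 1L
  }
  # fill background (all remaining zero rows) with zero-mean noise
  bg <- rowSums(app != 0) == 0
  if (any(bg)) {
    nbg <- sum(bg)
    blk <- .frameBlock(nbg, NA_character_, config, means)
    app[bg, ] <- blk$appearance
    mot[bg, ] <- blk$motion
  }
  list(appearance = app, motion = mot, fps = fps,
       truth = do.call(rbind, truth))
}

#' Simulate a skill/outcome cohort
#'
#' Draws records mirroring the outcome-association analysis: Z1 is a
#' high-skill probability in [0, 1], Z2 a surgeon caseload count, Z3 a
#' patient age, and the binary outcome Y (e.g. urinary continence
#' recovery at 3 months) is Bernoulli with
#' \code{plogis(b0 + b1 Z1 + b2 Z2 + b3 Z3)}.
#'
#' @param n number of records.
#' @param b0,b1,b2,b3 coefficients of the linear predictor.
#' @param seed RNG seed.
#' @param caseloadMean Poisson mean of the caseload distribution
#'   (default 100).
#' @param ageMean,ageSd normal parameters of patient age (defaults 64
#'   and 8 years).
#' @param nCases number of surgical cases the records are grouped into
#'   (default \code{n}, i.e. one record per case).
#' @return data.frame with columns \code{case_id}, \code{Z1},
#'   \code{Z2}, \code{Z3}, \code{Y}.
#' @export
genSkillOutcomeCohort <- function(n, b0 = 0, b1 = 0, b2 = 0, b3 = 0,
                                  seed = 1L, caseloadMean = 100,
                                  ageMean = 64, ageSd = 8, nCases = n) {
  set.seed(seed)
  idx <- sample(rep(seq_len(nCases), length.out = n))
  caseZ2 <- stats::rpois(nCases, caseloadMean)
  caseZ3 <- stats::rnorm(nCases, ageMean, ageSd)
  Z1 <- stats::runif(n)
  if (nCases == n) {
    eta <- b0 + b1 * Z1 + b2 * caseZ2[idx] + b3 * caseZ3[idx]
    Y <- stats::rbinom(n, 1, stats::plogis(eta))
  } else {
    # the outcome is a case-level quantity: one draw per case, from the
    # case's mean skill probability
    z1bar <- tapply(Z1, idx, mean)
    etaCase <- b0 + b1 * as.numeric(z1bar) + b2 * caseZ2[as.integer(names(z1bar))] +
      b3 * caseZ3[as.integer(names(z1bar))]
    caseY <- integer(nCases)
    caseY[as.integer(names(z1bar))] <- stats::rbinom(length(etaCase), 1,
                                                     stats::plogis(etaCase))
    Y <- caseY[idx]
  }
  data.frame(case_id = sprintf("case%05d", idx), Z1 = Z1, Z2 = caseZ2[idx],
             Z3 = caseZ3[idx], Y = Y, stringsAsFactors = FALSE)
}

#' Write a synthetic clip corpus to the feature-store formats
#'
#' Writes dense per-video streams into a [FeatureStore-class] and the
#' clip annotations as TSV, so the synthetic data flow through exactly
#' the same I/O surface as real extracted features.
#'
#' @param config a [syntheticConfig()].
#' @param storePath feature-store file path.
#' @param annotationPath annotation TSV path.
#' @param nVideos,clipsPerVideo corpus size.
#' @param seed base seed.
#' @return The annotation data.frame, invisibly.
#' @export
writeSyntheticCorpus <- function(config, storePath, annotationPath,
                                 nVideos = 4L, clipsPerVideo = 6L,
                                 seed = 1L) {
  store <- featureStore(storePath)
  ann <- list()
  k <- 0L
  for (v in seq_len(nVideos)) {
    vid <- sprintf("video%03d", v)
    appRows <- NULL; motRows <- NULL
    t0 <- 0
    for (cidx in seq_len(clipsPerVideo)) {
      k <- k + 1L
      cl <- config$categories[((k - 1L) %% length(config$categories)) + 1L]
      clip <- genClip(cl, config, videoId = vid, seed = .deriveSeed(seed, k),
                      startS = t0)
      appRows <- rbind(appRows, featureMatrix(clip@appearance))
      motRows <- rbind(motRows, featureMatrix(clip@motion))
      ann[[k]] <- data.frame(video_id = vid, start_s = t0,
                             end_s = clip@endS, category = cl,
                             stringsAsFactors = FALSE)
      t0 <- clip@endS
    }
    storeFeatures(store, vid, "appearance", appRows, fps = config$fps)
    storeFeatures(store, vid, "motion", motRows, fps = config$fps)
  }
  ann <- do.call(rbind, ann)
  writeClipAnnotations(ann, annotationPath)
  invisible(ann)
}
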