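# Default configuration for each pipeline command. Unknown keys in a
# user config are schema errors.
.pipelineDefaults <- function() {
  list(
    simulate = list(
      categories = c("hook", "clip", "cold_cut"), D = 32L, fps = 30,
      snr = 5, temporal_smoothness = 0.8, modality_correlation = 0.7,
      n_videos = 4L, clips_per_video = 6L, seed = 1L
    ),
    train = list(
      task = "gesture", D = 32L, E = 32L, n_layers = 1L, n_heads = 4L,
      max_T = 64L, dropout = 0.1, n_folds = 3L, n_epochs = 5L,
      batch_size = 8L, learning_rate = 0.1, class_balanced = TRUE,
      seed = 1L
    ),
    infer = list(
      regime = "gesture", tta_offsets = c(0L, 3L, 6L), S_thresh = NULL,
      chain_gap = NULL, video_id = NULL
    ),
    evaluate = list(overlap_frac = 0.10),
    explain = list(video_id = NULL, clip_index = 1L),
    outcomes = list(records = NULL, variant = "per-sample")
  )
}

# Merge user config and overrides onto the defaults; any key absent from
# the defaults is rejected by name.
.mergeConfig <- function(defaults, user, where) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s) in %s: %s", where,
                 paste(unknown, collapse = ", ")))
  for (k in names(user)) defaults[[k]] <- user[[k]]
  defaults
}

.configHash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f, version = 2)
  unname(tools::md5sum(f))
}

.writeManifest <- function(outDir, command, cfg, artifacts) {
  manifest <- list(
    command = command,
    config = cfg,
    config_hash = .configHash(cfg),
    artifacts = artifacts,
    package_version = as.character(utils::packageVersion("protoact")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(outDir, sprintf("manifest_%s.json", command))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Run one step of the decoding pipeline
#'
#' Single entry point wiring the workflow: \code{simulate} writes a
#' synthetic feature store and annotation table; \code{train} trains the
#' Monte Carlo ensemble on the store; \code{infer} decodes a full video
#' into events; \code{evaluate} reports cross-validated AUC/PPV;
#' \code{explain} writes per-frame attention weights for a clip;
#' \code{outcomes} fits the outcome-association model on a records TSV.
#' Each step writes its artifacts plus a JSON manifest (command, config
#' hash, package version, artifact paths) into \code{outDir}, and is
#' deterministic given its seeds.
#'
#' @param command one of \code{"simulate"}, \code{"train"},
#'   \code{"infer"}, \code{"evaluate"}, \code{"explain"},
#'   \code{"outcomes"}.
#' @param configPath optional YAML file with one top-level section per
#'   command; unknown keys are schema errors.
#' @param overrides named list overriding config values (highest
#'   precedence).
#' @param outDir run directory (created if missing); later steps read
#'   the artifacts of earlier ones from here.
#' @return Invisibly, the list of artifact paths written.
#' @export
runPipeline <- function(command = c("simulate", "train", "infer",
                                    "evaluate", "explain", "outcomes"),
                        configPath = NULL, overrides = list(),
                        outDir = "protoact_run") {
  command <- match.arg(command)
  defaults <- .pipelineDefaults()
  user <- list()
  if (!is.null(configPath)) {
    fileCfg <- yaml::read_yaml(configPath)
    unknown <- setdiff(names(fileCfg), names(defaults))
    if (length(unknown))
      stop(sprintf("unknown configuration section(s): %s",
                   paste(unknown, collapse = ", ")))
    if (!is.null(fileCfg[[command]])) user <- fileCfg[[command]]
  }
  cfg <- .mergeConfig(defaults[[command]], user, sprintf("'%s' config", command))
  cfg <- .mergeConfig(cfg, overrides, sprintf("'%s' overrides", command))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  storePath <- file.path(outDir, "features.rds")
  annPath <- file.path(outDir, "annotations.tsv")
  ckptDir <- file.path(outDir, "checkpoints")
  artifacts <- switch(command,
    simulate = {
      scfg <- syntheticConfig(categories = cfg$categories, D = cfg$D,
                              fps = cfg$fps, snr = cfg$snr,
                              temporal_smoothness = cfg$temporal_smoothness,
                              modality_correlation = cfg$modality_correlation,
                              seed = cfg$seed)
      writeSyntheticCorpus(scfg, storePath, annPath,
                           nVideos = cfg$n_videos,
                           clipsPerVideo = cfg$clips_per_video,
                           seed = cfg$seed)
      saveRDS(scfg, file.path(outDir, "synthetic_config.rds"))
      list(features = storePath, annotations = annPath)
    },
    train = {
      ann <- readClipAnnotations(annPath)
      store <- featureStore(storePath)
      samples <- lapply(seq_len(nrow(ann)), function(i)
        extractClip(store, ann$video_id[i], ann$start_s[i], ann$end_s[i],
                    task = cfg$task, category = ann$category[i]))
      splits <- makeSplits(unique(ann$video_id), nFolds = cfg$n_folds,
                           seed = cfg$seed)
      enc <- encoderConfig(D = cfg$D, E = cfg$E, n_layers = cfg$n_layers,
                           n_heads = cfg$n_heads, max_T = cfg$max_T,
                           dropout = cfg$dropout)
      tc <- trainConfig(batch_size = cfg$batch_size,
                        learning_rate = cfg$learning_rate,
                        n_epochs = cfg$n_epochs, seed = cfg$seed,
                        class_balanced = cfg$class_balanced)
      models <- trainEnsemble(samples, splits, enc, tc)
      if (!dir.exists(ckptDir)) dir.create(ckptDir)
      paths <- vapply(seq_along(models), function(f) {
        p <- file.path(ckptDir, sprintf("fold%02d.rds", f))
        saveCheckpoint(models[[f]], p)
        p
      }, character(1))
      writeSplits(splits, file.path(outDir, "splits.tsv"))
      saveRDS(splits, file.path(outDir, "splits.rds"))
      list(checkpoints = as.list(paths),
           splits = file.path(outDir, "splits.tsv"))
    },
    infer = {
      models <- lapply(list.files(ckptDir, full.names = TRUE, pattern = "\\.rds$"),
                       loadCheckpoint)
      if (!length(models)) stop("no checkpoints found; run 'train' first")
      C <- length(models[[1]]@categories)
      if (!is.null(cfg$S_thresh) && cfg$S_thresh > log(C))
        stop(sprintf("S_thresh = %.3f exceeds log(C) = %.3f; entropy can never exceed it",
                     cfg$S_thresh, log(C)))
      icfg <- inferenceConfig(regime = cfg$regime,
                              tta_offsets = cfg$tta_offsets,
                              S_thresh = cfg$S_thresh,
                              chain_gap = cfg$chain_gap,
                              n_folds = length(models))
      store <- featureStore(storePath)
      vids <- if (is.null(cfg$video_id)) unique(listFeatures(store)$video_id)
              else cfg$video_id
      paths <- character()
      for (vid in vids) {
        app <- loadFeatures(store, vid, "appearance")
        mot <- loadFeatures(store, vid, "motion")
        dec <- decodeVideo(app, mot, attr(app, "fps"), models, icfg)
        p <- file.path(outDir, sprintf("events_%s.tsv", vid))
        writeEvents(dec$events, vid, p)
        paths <- c(paths, p)
      }
      list(events = as.list(paths))
    },
    evaluate = {
      ann <- readClipAnnotations(annPath)
      store <- featureStore(storePath)
      tcfg <- .pipelineDefaults()$train
      samples <- lapply(seq_len(nrow(ann)), function(i)
        extractClip(store, ann$video_id[i], ann$start_s[i], ann$end_s[i],
                    task = tcfg$task, category = ann$category[i]))
      splits <- readRDS(file.path(outDir, "splits.rds"))
      models <- lapply(list.files(ckptDir, full.names = TRUE, pattern = "\\.rds$"),
                       loadCheckpoint)
      mr <- metricReport(samples, splits, models)
      p <- file.path(outDir, "metrics.json")
      jsonlite::write_json(list(
        auc_macro_mean = mr$auc_macro$mean, auc_macro_sd = mr$auc_macro$sd,
        ppv_mean = mr$ppv$mean, ppv_sd = mr$ppv$sd
      ), p, auto_unbox = TRUE, digits = NA)
      list(metrics = p)
    },
    explain = {
      ann <- readClipAnnotations(annPath)
      store <- featureStore(storePath)
      models <- lapply(list.files(ckptDir, full.names = TRUE, pattern = "\\.rds$"),
                       loadCheckpoint)
      if (!length(models)) stop("no checkpoints found; run 'train' first")
      i <- cfg$clip_index
      s <- extractClip(store, ann$video_id[i], ann$start_s[i], ann$end_s[i],
                       task = .pipelineDefaults()$train$task,
                       category = ann$category[i])
      w <- frameImportance(s, models[[1]])
      p <- file.path(outDir, "frame_importance.csv")
      utils::write.csv(data.frame(frame = s@appearance@frameIndices,
                                  weight = w), p, row.names = FALSE)
      list(frame_importance = p)
    },
    outcomes = {
      if (is.null(cfg$records)) stop("outcomes requires a 'records' TSV path")
      rec <- readOutcomeRecords(cfg$records)
      if (cfg$variant == "per-case") rec <- aggregateCase(rec)
      fitObj <- fitOutcomeModel(rec, variant = cfg$variant)
      p <- file.path(outDir, "outcome_fit.json")
      writeOutcomeFit(fitObj, p)
      list(outcome_fit = p)
    }
  )
  .writeManifest(outDir, command, cfg, artifacts)
  invisible(artifacts)
}
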