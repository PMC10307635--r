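test_that("clip generation is a pure function of config and seed", {
  cfg <- syntheticConfig(categories = c("hook", "clip"), D = 8, seed = 3)
  s1 <- genClip("hook", cfg, seed = 11)
  s2 <- genClip("hook", cfg, seed = 11)
  expect_identical(featureMatrix(appearanceSeq(s1)),
                   featureMatrix(appearanceSeq(s2)))
  expect_identical(featureMatrix(motionSeq(s1)), featureMatrix(motionSeq(s2)))
  s3 <- genClip("hook", cfg, seed = 12)
  expect_false(identical(featureMatrix(appearanceSeq(s1)),
                         featureMatrix(appearanceSeq(s3))))
  expect_identical(category(s1), "hook")
  expect_error(genClip("unknown", cfg), "unknown category")
})

test_that("zero snr removes any class signal from the streams", {
  cfg <- syntheticConfig(categories = c("A", "B"), D = 8, snr = 0, seed = 5,
                         duration_range = c(1, 1))
  # projection of per-clip mean frames onto the A-B mean-difference axis
  means <- pa$.classMeans(cfg)
  axis <- means[1, ] - means[2, ]
  proj <- function(cl, seeds) vapply(seeds, function(s)
    sum(colMeans(featureMatrix(appearanceSeq(genClip(cl, cfg, seed = s)))) * axis),
    numeric(1))
  pA <- proj("A", 1:100)
  pB <- proj("B", 101:200)
  expect_gt(t.test(pA, pB)$p.value, 0.01)
})

test_that("high snr clips are linearly separable from mean frame vectors", {
  cfg <- syntheticConfig(categories = c("A", "B"), D = 32, snr = 5, seed = 6,
                         temporal_smoothness = 0.8, duration_range = c(1, 2))
  means <- pa$.classMeans(cfg)
  lab <- rep(c("A", "B"), each = 100)
  X <- t(vapply(seq_along(lab), function(i)
    colMeans(featureMatrix(appearanceSeq(genClip(lab[i], cfg, seed = 1000 + i)))),
    numeric(32)))
  # nearest-class-mean probe in the generator's own geometry
  dA <- X %*% means[1, ] - X %*% means[2, ]
  pred <- ifelse(dA > 0, "A", "B")
  expect_gte(mean(pred == lab), 0.95)
})

test_that("motion streams track appearance streams by the set correlation", {
  cfg <- syntheticConfig(categories = c("A", "B"), D = 16, snr = 0,
                         modality_correlation = 0.9, seed = 7,
                         duration_range = c(4, 4))
  s <- genClip("A", cfg, seed = 3)
  r <- cor(as.numeric(featureMatrix(appearanceSeq(s))),
           as.numeric(featureMatrix(motionSeq(s))))
  expect_gt(r, 0.8)
  cfg0 <- syntheticConfig(categories = c("A", "B"), D = 16, snr = 0,
                          modality_correlation = 0, seed = 7,
                          duration_range = c(4, 4))
  s0 <- genClip("A", cfg0, seed = 3)
  r0 <- cor(as.numeric(featureMatrix(appearanceSeq(s0))),
            as.numeric(featureMatrix(motionSeq(s0))))
  expect_lt(abs(r0), 0.2)
})

test_that("timelines plant the motif in order with background in between", {
  cfg <- syntheticConfig(categories = c("hook", "clip", "cold_cut"),
                         D = 8, snr = 3, seed = 8,
                         duration_range = c(1, 2), gap_range = c(2, 4),
                         motif = c("hook", "clip", "cold_cut"))
  tl <- genTimeline(120, cfg, seed = 9)
  expect_identical(ncol(tl$appearance), 8L)
  expect_identical(nrow(tl$appearance), as.integer(120 * cfg$fps))
  expect_gt(nrow(tl$truth), 3)
  # event order cycles hook -> clip -> cold_cut
  expected <- rep(c("hook", "clip", "cold_cut"), length.out = nrow(tl$truth))
  expect_identical(tl$truth$category, expected)
  expect_true(all(tl$truth$end_s > tl$truth$start_s))
  expect_true(all(diff(tl$truth$start_s) > 0))
  # truth feeds the segment metric directly
  expect_equal(segmentalF1(tl$truth, tl$truth), 100)
  # determinism
  tl2 <- genTimeline(120, cfg, seed = 9)
  expect_identical(tl$appearance, tl2$appearance)
  expect_identical(tl$truth, tl2$truth)
})

test_that("single-event grammars yield exactly one truth interval", {
  cfg <- syntheticConfig(categories = c("only", "other"), D = 4, snr = 2,
                         seed = 10, duration_range = c(2, 3),
                         gap_range = c(2, 3), motif = "only")
  tl <- genTimeline(8, cfg, seed = 2)
  expect_identical(nrow(tl$truth), 1L)
  expect_identical(tl$truth$category, "only")
})

test_that("a designated background category carries no class signal", {
  cfg <- syntheticConfig(categories = c("hook", "background"), D = 8, snr = 5,
                         seed = 11, background = "background")
  means <- pa$.classMeans(cfg)
  expect_true(all(means[2, ] == 0))
  expect_error(
    syntheticConfig(categories = c("a", "b"), background = "zz"),
    "must be listed")
  expect_error(
    syntheticConfig(categories = c("a", "b"), motif = c("a", "b"),
                    background = "b"),
    "cannot be part of the motif")
})

test_that("outcome cohorts follow the configured logistic model", {
  co <- genSkillOutcomeCohort(4000, b0 = 0, seed = 12)
  expect_equal(mean(co$Y), 0.5, tolerance = 0.03)
  expect_true(all(co$Z1 >= 0 & co$Z1 <= 1))
  expect_true(all(co$Z2 >= 0))
  expect_true(all(co$Y %in% c(0, 1)))
  expect_identical(genSkillOutcomeCohort(50, b1 = 1, seed = 13),
                   genSkillOutcomeCohort(50, b1 = 1, seed = 13))
  # grouped cohorts keep case-level quantities constant within case
  grp <- genSkillOutcomeCohort(200, b1 = 0.5, seed = 14, nCases = 40)
  byCase <- split(grp, grp$case_id)
  expect_true(all(vapply(byCase, function(df)
    length(unique(df$Y)) == 1 && length(unique(df$Z2)) == 1, logical(1))))
})

test_that("synthetic corpora flow through the feature-store interfaces", {
  cfg <- syntheticConfig(categories = c("a", "b"), D = 6, snr = 2, seed = 15,
                         duration_range = c(0.5, 1))
  storePath <- tempfile(fileext = ".rds")
  annPath <- tempfile(fileext = ".tsv")
  ann <- writeSyntheticCorpus(cfg, storePath, annPath, nVideos = 2,
                              clipsPerVideo = 4, seed = 15)
  back <- readClipAnnotations(annPath)
  expect_identical(nrow(back), 8L)
  store <- featureStore(storePath)
  s <- extractClip(store, back$video_id[1], back$start_s[1], back$end_s[1],
                   task = "gesture", category = back$category[1])
  expect_s4_class(s, "VideoSample")
  expect_identical(ncol(featureMatrix(appearanceSeq(s))), 6L)
})
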