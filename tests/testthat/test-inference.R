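test_that("window curation follows the two subphase approaches and 1-s gestures", {
  w <- curateWindows(20, "subphase")
  a1 <- w[w$approach == 1, ]
  a2 <- w[w$approach == 2, ]
  expect_equal(a1$start_s, c(0, 5, 10))
  expect_equal(a1$end_s, c(10, 15, 20))
  expect_equal(a2$start_s, c(0, 5, 10, 15))
  expect_equal(a2$end_s, c(5, 10, 15, 20))
  g <- curateWindows(3, "gesture")
  expect_equal(g$start_s, c(0, 1, 2))
  expect_equal(g$end_s, c(1, 2, 3))
  expect_warning(out <- curateWindows(0.5, "gesture"), "shorter")
  expect_identical(nrow(out), 0L)
  expect_error(curateWindows(0, "gesture"), "positive")
})

test_that("every 10-s timespan on the 5-s grid is covered by 3 windows", {
  w <- curateWindows(40, "subphase")
  for (g in seq(0, 30, by = 5)) {
    n <- sum(w$approach == 1 & w$start_s == g) +
      sum(w$approach == 2 & w$start_s %in% c(g, g + 5))
    expect_identical(n, 3L)
  }
})

test_that("TTA inputs shift the sampling grid by the configured offsets", {
  sets <- ttaFrameIndices(90, "subphase")
  expect_equal(sets[[1]], as.integer(10 * (0:8)))
  expect_equal(sets[[2]], as.integer(3 + 10 * (0:8)))
  expect_equal(sets[[3]], as.integer(6 + 10 * (0:8)))
  # stride 10 with offsets 0/3/6: the three variants share no index
  expect_length(intersect(sets[[1]], union(sets[[2]], sets[[3]])), 0)
  expect_length(intersect(sets[[2]], sets[[3]]), 0)
  single <- ttaFrameIndices(90, "subphase", offsets = 0L)
  expect_length(single, 1)
  expect_equal(single[[1]], sampleFrameIndices("subphase_or_skill", 90))
})

test_that("bagging averages masses for a common timespan", {
  mk <- function(p) list(probs = p, timespan = c(0, 10))
  expect_equal(bagCells(list(mk(c(1, 0)), mk(c(0, 1)))), c(0.5, 0.5))
  expect_equal(bagCells(list(mk(c(0.3, 0.7)), mk(c(0.3, 0.7)))), c(0.3, 0.7))
  expect_equal(sum(bagCells(lapply(1:5, function(i) {
    x <- runif(3); mk(x / sum(x))
  }))), 1, tolerance = 1e-9)
  bad <- list(mk(c(1, 0)), list(probs = c(1, 0), timespan = c(5, 15)))
  expect_error(bagCells(bad), "mixed timespans")
  expect_error(bagCells(list()), "at least one")
})

test_that("entropy abstention keeps confident masses and drops uniform ones", {
  u6 <- rep(1 / 6, 6)
  res <- entropyAbstain(u6, 1.74, letters[1:6])
  expect_equal(res$entropy, log(6), tolerance = 1e-12)
  expect_false(res$keep)
  expect_true(is.na(res$label))
  oneHot <- c(1, 0, 0, 0, 0, 0)
  res <- entropyAbstain(oneHot, 1.74, letters[1:6])
  expect_identical(res$entropy, 0)
  expect_true(res$keep)
  expect_identical(res$label, "a")
  # gesture default threshold is 1.74
  expect_equal(inferenceConfig("gesture")$S_thresh, 1.74)
})

test_that("abstention is monotone in the threshold", {
  set.seed(31)
  for (i in 1:50) {
    p <- runif(6); p <- p / sum(p)
    t1 <- runif(1, 0, log(6)); t2 <- runif(1, t1, log(6))
    k1 <- entropyAbstain(p, t1)$keep
    k2 <- entropyAbstain(p, t2)$keep
    expect_true(!k1 || k2)  # raising the threshold never drops a kept mass
  }
})

test_that("event chaining reproduces the worked retraction example", {
  preds <- data.frame(start_s = c(10, 11, 15), end_s = c(11, 12, 16),
                      category = "retraction")
  ev <- chainEvents(preds, chainGap = 2)
  expect_identical(nrow(ev), 2L)
  expect_equal(ev$start_s, c(10, 15))
  expect_equal(ev$end_s, c(12, 16))
  # the subphase regime defaults to a 3-s gap
  expect_equal(inferenceConfig("subphase")$chain_gap, 3)
  expect_equal(inferenceConfig("gesture")$chain_gap, 2)
})

test_that("chaining is idempotent, category-safe and unions overlaps", {
  preds <- data.frame(
    start_s = c(0, 0.5, 4, 10, 10),
    end_s = c(1, 2, 5, 11, 11),
    category = c("a", "a", "a", "a", "b"))
  ev <- chainEvents(preds, chainGap = 2)
  expect_identical(chainEvents(ev, 2), ev)
  expect_identical(nrow(ev[ev$category == "b", ]), 1L)
  # overlapping [0,1] and [0.5,2] union; the gap to [4,5] is exactly 2,
  # which does not merge (merging requires gap strictly below chainGap)
  aEv <- ev[ev$category == "a", ]
  expect_identical(nrow(aEv), 3L)
  expect_equal(aEv$start_s[1], 0)
  expect_equal(aEv$end_s[1], 2)
  # a wider gap does merge them
  aEv3 <- chainEvents(preds, chainGap = 2.5)
  expect_equal(aEv3$end_s[aEv3$category == "a"][1], 5)
  # per-category events disjoint and sorted
  set.seed(32)
  rnd <- data.frame(start_s = runif(40, 0, 100), category = sample(c("x", "y"), 40, TRUE))
  rnd$end_s <- rnd$start_s + runif(40, 0.5, 5)
  ev2 <- chainEvents(rnd, chainGap = 1.5)
  for (cl in unique(ev2$category)) {
    e <- ev2[ev2$category == cl, ]
    expect_true(all(diff(e$start_s) > 0))
    if (nrow(e) > 1) expect_true(all(e$start_s[-1] >= e$end_s[-nrow(e)]))
    expect_lte(sum(e$end_s - e$start_s), 100 + 5)
  }
  expect_identical(chainEvents(ev2, 1.5), ev2)
})

test_that("activity profiles report the low-skill ratio", {
  ev <- data.frame(category = rep("needle_handling", 4),
                   start_s = c(0, 10, 20, 30), end_s = c(5, 15, 25, 35))
  prof <- activityProfile(ev, skillLabels = c("low", "high", "high", "high"))
  expect_equal(prof$low_skill_ratio, 0.25)
  expect_equal(activityProfile(ev, rep("low", 4))$low_skill_ratio, 1)
  none <- ev[0, ]
  expect_null(activityProfile(none, character(0))$low_skill_ratio)
})

test_that("the subphase ensemble accumulates 3 windows x folds x TTAs per timespan", {
  set.seed(33)
  models <- lapply(1:4, function(i)
    toyDecoder(D = 6, E = 16, n_layers = 1, n_heads = 2, max_T = 40,
               categories = c("NH", "ND", "NW"), seed = i))
  fps <- 10
  app <- matrix(rnorm(fps * 30 * 6), fps * 30, 6)
  mot <- matrix(rnorm(fps * 30 * 6), fps * 30, 6)
  dec <- decodeVideo(app, mot, fps, models,
                     inferenceConfig("subphase", S_thresh = log(3)))
  # every 10-s timespan: (1 approach-1 + 2 approach-2 windows) x 4 folds x 3 TTA
  expect_true(all(dec$n_cells == 3 * 4 * 3))
  expect_true(all(abs(rowSums(as.matrix(dec$bagged[, models[[1]]@categories])) - 1) < 1e-9))
})

test_that("full-video decoding is deterministic given fixed checkpoints", {
  set.seed(34)
  models <- lapply(1:2, function(i)
    toyDecoder(D = 6, E = 16, n_layers = 1, n_heads = 2, max_T = 40,
               categories = c("a", "b", "c"), seed = i))
  fps <- 10
  app <- matrix(rnorm(fps * 20 * 6), fps * 20, 6)
  mot <- matrix(rnorm(fps * 20 * 6), fps * 20, 6)
  cfg <- inferenceConfig("gesture", S_thresh = 0.95 * log(3))
  d1 <- decodeVideo(app, mot, fps, models, cfg)
  d2 <- decodeVideo(app, mot, fps, models, cfg)
  expect_identical(d1$events, d2$events)
  expect_identical(d1$bagged, d2$bagged)
})
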