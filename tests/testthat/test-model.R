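test_that("toy single-head encoder matches a dense attention oracle", {
  set.seed(11)
  dec <- toyDecoder(D = 4, E = 8, n_layers = 1, n_heads = 1, seed = 3)
  X <- matrix(rnorm(8), 2, 4)
  fs <- FrameFeatureSequence(X, "appearance", fps = 30)
  h <- encodeModality(fs, dec)
  cfg <- dec@config
  class(cfg) <- "encoderConfig"
  expect_lt(max(abs(h - denseAttentionOracle(X, dec@params, cfg))), 1e-9)
})

test_that("padding with zero rows never changes the encoding", {
  set.seed(12)
  dec <- toyDecoder(D = 8, E = 8, n_layers = 2, n_heads = 2, seed = 5)
  for (trial in 1:20) {
    Tn <- sample(2:10, 1)
    s <- randomSample(Tn, 8)
    sPad <- pa$.padSample(s, Tn + sample(1:8, 1))
    h1 <- pa$.sampleForward(s, dec@params, dec@config)$hVideo
    h2 <- pa$.sampleForward(sPad, dec@params, dec@config)$hVideo
    expect_lt(max(abs(h1 - h2)), 1e-6)
  }
})

test_that("sequences beyond the positional capacity raise a capacity error", {
  dec <- toyDecoder(D = 4, E = 8, max_T = 6, seed = 2)
  s <- randomSample(7, 4)
  expect_error(encodeModality(appearanceSeq(s), dec), "max_T")
})

test_that("the mean-pooling ablation is permutation invariant, attention is not", {
  set.seed(13)
  X <- matrix(rnorm(6 * 8), 6, 8)
  perm <- sample(6)
  mk <- function(m) FrameFeatureSequence(m, "appearance", fps = 30)
  noSA <- newActivityDecoder(
    encoderConfig(D = 8, E = 8, n_layers = 1, n_heads = 2, max_T = 16,
                  dropout = 0, use_self_attention = FALSE),
    c("a", "b"), seed = 4)
  expect_equal(encodeModality(mk(X), noSA), colMeans(X))
  expect_equal(encodeModality(mk(X[perm, ]), noSA),
               encodeModality(mk(X), noSA))
  # with positional embeddings the attention encoder is order sensitive
  withPos <- toyDecoder(D = 8, E = 8, n_layers = 1, n_heads = 2, seed = 4)
  expect_gt(max(abs(encodeModality(mk(X[perm, ]), withPos) -
                    encodeModality(mk(X), withPos))), 1e-4)
  # without them it is order invariant
  noPos <- newActivityDecoder(
    encoderConfig(D = 8, E = 8, n_layers = 1, n_heads = 2, max_T = 16,
                  dropout = 0, use_positional = FALSE),
    c("a", "b"), seed = 4)
  expect_lt(max(abs(encodeModality(mk(X[perm, ]), noPos) -
                    encodeModality(mk(X), noPos))), 1e-9)
})

test_that("modality aggregation is an elementwise sum", {
  x <- rnorm(5); y <- rnorm(5)
  expect_identical(aggregateModalities(x, rep(0, 5)), x)
  expect_identical(aggregateModalities(x, y), aggregateModalities(y, x))
  expect_identical(aggregateModalities(c(1, 2), c(3, 4)), c(4, 6))
  expect_error(aggregateModalities(1:3, 1:4), "length")
})

test_that("projection maps D to E deterministically", {
  dec <- toyDecoder(D = 6, E = 4, seed = 9)
  v <- rnorm(6)
  expect_length(projectEmbedding(v, dec), 4)
  expect_identical(projectEmbedding(v, dec), projectEmbedding(v, dec))
  expect_error(projectEmbedding(c(v[-1], NA), dec), "non-finite")
  # with zero biases a zero input stays zero through linear-ReLU-linear
  dec@params$c1p[] <- 0; dec@params$c2p[] <- 0
  expect_equal(projectEmbedding(rep(0, 6), dec), rep(0, 4))
})

test_that("prototype classification is a softmax over cosine similarities", {
  bank <- PrototypeBank(rbind(c(1, 0), c(0, 1)), c("a", "b"))
  p <- classifyEmbedding(c(1, 0), bank)
  # cosines are (1, 0): softmax gives (e/(e+1), 1/(e+1))
  expect_equal(as.numeric(p), c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-9)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_identical(attr(p, "label"), "a")
  # cosine scale invariance
  expect_equal(as.numeric(classifyEmbedding(c(10, 0), bank)), as.numeric(p),
               tolerance = 1e-12)
  # identical prototypes give the uniform mass
  same <- PrototypeBank(rbind(c(1, 1), c(1, 1), c(1, 1)), c("a", "b", "c"))
  expect_equal(as.numeric(classifyEmbedding(c(2, -1), same)), rep(1 / 3, 3))
  expect_error(classifyEmbedding(c(0, 0), bank), "zero-norm")
})

test_that("the contrastive loss matches its closed forms", {
  bank <- PrototypeBank(rbind(c(1, 0), c(-1, 0)), c("pos", "neg"))
  # s(h, p_c) = 1, s(h, p_other) = -1: loss is -log(e / (e + 1/e))
  expect_equal(infoNCELoss(matrix(c(1, 0), 1), "pos", bank),
               -log(exp(1) / (exp(1) + exp(-1))), tolerance = 1e-12)
  # equal similarities: loss = B log C
  same <- PrototypeBank(rbind(c(1, 1), c(1, 1), c(1, 1)), c("a", "b", "c"))
  H <- matrix(rnorm(4 * 2), 4, 2)
  expect_equal(infoNCELoss(H, rep("b", 4), same), 4 * log(3), tolerance = 1e-9)
  expect_error(infoNCELoss(H, rep("zz", 4), same), "without a prototype")
  expect_gte(infoNCELoss(H, rep("a", 4), same), 0)
})

test_that("the contrastive loss equals a brute-force transcription", {
  set.seed(21)
  for (trial in 1:25) {
    B <- sample(1:6, 1); C <- sample(2:5, 1); E <- sample(2:6, 1)
    H <- matrix(rnorm(B * E), B, E)
    P <- matrix(rnorm(C * E), C, E)
    cats <- letters[1:C]
    labels <- sample(cats, B, replace = TRUE)
    bank <- PrototypeBank(P, cats)
    ours <- infoNCELoss(H, labels, bank)
    brute <- bruteInfoNCE(H, labels, P, cats)
    expect_lt(abs(ours - brute) / max(abs(brute), 1e-12), 1e-9)
  }
})

test_that("analytic loss gradients match finite differences", {
  set.seed(22)
  B <- 3; C <- 4; E <- 5
  H <- matrix(rnorm(B * E), B, E)
  P <- matrix(rnorm(C * E), C, E)
  ci <- sample(C, B, replace = TRUE)
  res <- pa$.infoNCE(H, ci, P)
  eps <- 1e-6
  for (j in seq_len(C * E)) {
    Pp <- P; Pp[j] <- Pp[j] + eps
    Pm <- P; Pm[j] <- Pm[j] - eps
    fd <- (pa$.infoNCE(H, ci, Pp)$loss - pa$.infoNCE(H, ci, Pm)$loss) / (2 * eps)
    expect_lt(abs(fd - res$dP[j]) / max(abs(fd), abs(res$dP[j]), 1e-6), 1e-4)
  }
  for (j in seq_len(B * E)) {
    Hp <- H; Hp[j] <- Hp[j] + eps
    Hm <- H; Hm[j] <- Hm[j] - eps
    fd <- (pa$.infoNCE(Hp, ci, P)$loss - pa$.infoNCE(Hm, ci, P)$loss) / (2 * eps)
    expect_lt(abs(fd - res$dH[j]) / max(abs(fd), abs(res$dH[j]), 1e-6), 1e-4)
  }
})

test_that("end-to-end backpropagation matches finite differences", {
  set.seed(23)
  cfg <- unclass(encoderConfig(D = 4, E = 8, n_layers = 2, n_heads = 2,
                               max_T = 8, dropout = 0))
  params <- pa$.initParams(cfg, 3)
  samples <- list(randomSample(3, 4), pa$.padSample(randomSample(2, 4), 3))
  ci <- c(1L, 3L)
  lossOf <- function(p) {
    H <- t(vapply(samples, function(s)
      pa$.sampleForward(s, p, cfg)$hVideo, numeric(cfg$E)))
    pa$.infoNCE(H, ci, p$proto)$loss
  }
  fws <- lapply(samples, function(s)
    pa$.sampleForward(s, params, cfg, keepCache = TRUE))
  H <- t(vapply(fws, function(f) f$hVideo, numeric(cfg$E)))
  nce <- pa$.infoNCE(H, ci, params$proto)
  grads <- pa$.zeroLike(params)
  grads$proto <- grads$proto + nce$dP
  for (i in 1:2)
    grads <- pa$.sampleBackward(nce$dH[i, ], fws[[i]], samples[[i]],
                                params, cfg, grads)
  eps <- 1e-6
  modifyIn <- function(lst, path, value) {
    if (length(path) == 1) { lst[[path[[1]]]] <- value; return(lst) }
    lst[[path[[1]]]] <- modifyIn(lst[[path[[1]]]], path[-1], value)
    lst
  }
  leaves <- c(list("e_cls", "pos", "P1", "c1p", "P2", "c2p", "proto"),
              unlist(lapply(1:2, function(l)
                lapply(c("Wq", "Wv", "Wo", "g1", "W1", "W2", "g2", "be2"),
                       function(w) list("layers", l, w))), recursive = FALSE))
  for (leaf in leaves) {
    path <- as.list(leaf)
    p0 <- params; g <- grads
    for (nm in path) { p0 <- p0[[nm]]; g <- g[[nm]] }
    for (j in sample(length(p0), min(4, length(p0)))) {
      x <- p0; x[j] <- x[j] + eps
      up <- lossOf(modifyIn(params, path, x))
      x <- p0; x[j] <- x[j] - eps
      dn <- lossOf(modifyIn(params, path, x))
      fd <- (up - dn) / (2 * eps)
      # skip gradients that are identically ~0 (FD noise dominates)
      if (max(abs(fd), abs(g[j])) < 1e-6) next
      expect_lt(abs(fd - g[j]) / max(abs(fd), abs(g[j])), 1e-4)
    }
  }
})

test_that("frame importance is a mass over valid frames", {
  set.seed(24)
  dec <- toyDecoder(D = 8, E = 8, n_layers = 2, n_heads = 2, seed = 6)
  s <- pa$.padSample(randomSample(5, 8), 8)
  w <- frameImportance(s, dec)
  expect_length(w, 8)
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_true(all(w[6:8] == 0))
  s1 <- randomSample(1, 8)
  expect_equal(frameImportance(s1, dec), 1)
  noSA <- newActivityDecoder(
    encoderConfig(D = 8, E = 8, n_layers = 1, n_heads = 2, max_T = 16,
                  dropout = 0, use_self_attention = FALSE),
    c("a", "b"), seed = 4)
  expect_error(frameImportance(s, noSA), "self-attention")
})

test_that("checkpoints roundtrip through disk", {
  dec <- toyDecoder(seed = 31)
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(dec, path)
  back <- loadCheckpoint(path)
  expect_identical(back@params, dec@params)
  expect_identical(back@categories, dec@categories)
  s <- randomSample(4, 8)
  expect_identical(predictSample(s, back), predictSample(s, dec))
})
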