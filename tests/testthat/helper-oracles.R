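# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (loops, closed forms) and share no code
# with the implementation they check.

pa <- asNamespace("protoact")

# Random video sample with equal-length appearance/motion streams.
randomSample <- function(Tn, D, fps = 30, category = "a", videoId = "v") {
  VideoSample(videoId, 0, Tn / fps,
    FrameFeatureSequence(matrix(rnorm(Tn * D), Tn, D), "appearance", fps = fps),
    FrameFeatureSequence(matrix(rnorm(Tn * D), Tn, D), "motion", fps = fps),
    category = category)
}

# Toy deterministic parameters (no randomness) for a given config.
toyDecoder <- function(D = 8, E = 8, n_layers = 1, n_heads = 1, max_T = 32,
                       categories = c("a", "b"), seed = 7) {
  cfg <- encoderConfig(D = D, E = E, n_layers = n_layers, n_heads = n_heads,
                       max_T = max_T, dropout = 0)
  newActivityDecoder(cfg, categories, seed = seed)
}

# Brute-force InfoNCE: direct transcription of the contrastive objective,
# sum over the batch of -log softmax(cosine scores)[true class].
bruteInfoNCE <- function(H, labels, prototypes, categoryNames) {
  total <- 0
  for (i in seq_len(nrow(H))) {
    h <- H[i, ]
    s <- numeric(nrow(prototypes))
    for (j in seq_len(nrow(prototypes))) {
      p <- prototypes[j, ]
      s[j] <- sum(h * p) / (sqrt(sum(h^2)) * sqrt(sum(p^2)))
    }
    c_i <- which(categoryNames == labels[i])
    total <- total - log(exp(s[c_i]) / sum(exp(s)))
  }
  total
}

# Dense single-head attention oracle for a 1-layer encoder without any
# masking shortcuts: recomputes the whole forward pass from the raw
# parameter list for an all-valid sequence.
denseAttentionOracle <- function(X, params, cfg) {
  lnorm <- function(x, g, b) {
    mu <- mean(x); s <- sqrt(mean((x - mu)^2) + 1e-5)
    g * (x - mu) / s + b
  }
  Tn <- nrow(X)
  Z <- rbind(params$e_cls, X + params$pos[seq_len(Tn), , drop = FALSE])
  L <- params$layers[[1]]
  Q <- Z %*% L$Wq + matrix(L$bq, Tn + 1, cfg$D, byrow = TRUE)
  K <- Z %*% L$Wk + matrix(L$bk, Tn + 1, cfg$D, byrow = TRUE)
  V <- Z %*% L$Wv + matrix(L$bv, Tn + 1, cfg$D, byrow = TRUE)
  S <- Q %*% t(K) / sqrt(cfg$D)
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  M <- (A %*% V) %*% L$Wo + matrix(L$bo, Tn + 1, cfg$D, byrow = TRUE)
  X1 <- t(sapply(seq_len(Tn + 1), function(i) lnorm(Z[i, ] + M[i, ], L$g1, L$be1)))
  Ff <- pmax(X1 %*% L$W1 + matrix(L$c1, Tn + 1, ncol(L$W1), byrow = TRUE), 0) %*%
    L$W2 + matrix(L$c2, Tn + 1, cfg$D, byrow = TRUE)
  X2 <- t(sapply(seq_len(Tn + 1), function(i) lnorm(X1[i, ] + Ff[i, ], L$g2, L$be2)))
  X2[1, ]
}

# Pairwise-comparison (Mann-Whitney) AUC oracle.
bruteAUC <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

iouOf <- function(a0, a1, b0, b1) {
  i <- max(0, min(a1, b1) - max(a0, b0))
  u <- (a1 - a0) + (b1 - b0) - i
  if (u <= 0) 0 else i / u
}

# Exhaustive optimal segment matching: maximum number of one-to-one
# same-category pairs with IoU >= k, over all assignments.
bruteSegF1 <- function(pred, truth, k) {
  tp <- 0
  for (cl in unique(c(pred$category, truth$category))) {
    p <- pred[pred$category == cl, , drop = FALSE]
    g <- truth[truth$category == cl, , drop = FALSE]
    if (!nrow(p) || !nrow(g)) next
    ok <- outer(seq_len(nrow(p)), seq_len(nrow(g)), Vectorize(function(i, j)
      iouOf(p$start_s[i], p$end_s[i], g$start_s[j], g$end_s[j]) >= k))
    ok <- rbind(ok)
    # exhaustive maximum bipartite matching by recursion over truths
    maxMatch <- function(j, used) {
      if (j > nrow(g)) return(0)
      best <- maxMatch(j + 1, used)           # leave truth j unmatched
      for (i in which(ok[, j] & !used)) {
        u <- used; u[i] <- TRUE
        best <- max(best, 1 + maxMatch(j + 1, u))
      }
      best
    }
    tp <- tp + maxMatch(1, rep(FALSE, nrow(p)))
  }
  fp <- nrow(pred) - tp
  fn <- nrow(truth) - tp
  if (tp + fp + fn == 0) return(100)
  100 * 2 * tp / (2 * tp + fp + fn)
}

# Fraction of ground-truth events recovered by a same-category decoded
# event at the given IoU threshold.
eventRecovery <- function(events, truth, k = 0.1) {
  mean(vapply(seq_len(nrow(truth)), function(j) {
    p <- events[events$category == truth$category[j], , drop = FALSE]
    if (!nrow(p)) return(FALSE)
    any(vapply(seq_len(nrow(p)), function(i)
      iouOf(p$start_s[i], p$end_s[i], truth$start_s[j], truth$end_s[j]) >= k,
      logical(1)))
  }, logical(1)))
}
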