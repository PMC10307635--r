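#' Encoder configuration
#'
#' Configuration of the two-stream temporal transformer. The encoder
#' parameters (and, by default, the classification-token and positional
#' embeddings) are shared across the appearance and motion streams.
#'
#' @param D input feature dimension (default 384, the dimension produced
#'   by the frozen spatial feature extractor).
#' @param E projection/prototype dimension (default 256).
#' @param n_layers number of transformer encoder layers (default 4).
#' @param n_heads attention heads; must divide \code{D} (default 8).
#' @param max_T positional-embedding capacity in frames (default 512);
#'   longer sequences raise an error.
#' @param ff_mult width multiplier of the position-wise feed-forward
#'   layer (default 4, i.e. hidden width \code{4 * D}).
#' @param dropout dropout rate applied to each sub-layer output during
#'   training (default 0.1).
#' @param use_self_attention ablation switch; when \code{FALSE} the
#'   encoder is replaced by a mean over valid frame features.
#' @param use_positional whether learned temporal positional embeddings
#'   are added to the frame features (default \code{TRUE}).
#' @param modalities character subset of \code{c("appearance","motion")}
#'   (ablation switch); the missing stream contributes a zero vector.
#' @return A validated list of class \code{"encoderConfig"}.
#' @export
encoderConfig <- function(D = 384L, E = 256L, n_layers = 4L, n_heads = 8L,
                          max_T = 512L, ff_mult = 4L, dropout = 0.1,
                          use_self_attention = TRUE, use_positional = TRUE,
                          modalities = c("appearance", "motion")) {
  cfg <- list(
    D = as.integer(D), E = as.integer(E), n_layers = as.integer(n_layers),
    n_heads = as.integer(n_heads), max_T = as.integer(max_T),
    ff_mult = as.integer(ff_mult), dropout = as.numeric(dropout),
    use_self_attention = isTRUE(use_self_attention),
    use_positional = isTRUE(use_positional),
    modalities = match.arg(modalities, several.ok = TRUE)
  )
  if (cfg$D < 1 || cfg$E < 1) stop("D and E must be positive")
  if (cfg$D %% cfg$n_heads != 0) stop("D must be divisible by n_heads")
  if (cfg$n_layers < 1) stop("n_layers must be >= 1")
  if (cfg$max_T < 1) stop("max_T must be >= 1")
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must be in [0, 1)")
  if (!length(cfg$modalities)) stop("at least one modality is required")
  class(cfg) <- "encoderConfig"
  cfg
}

# Glorot-uniform weight matrix.
.glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

# Initialize all learnable parameters: cls embedding, positional
# embeddings, encoder layers, projection head and prototypes. Uses the
# current RNG state.
.initParams <- function(cfg, nCategories) {
  D <- cfg$D; E <- cfg$E; Dff <- cfg$ff_mult * D
  layers <- lapply(seq_len(cfg$n_layers), function(l) {
    list(
      Wq = .glorot(D, D), bq = numeric(D),
      Wk = .glorot(D, D), bk = numeric(D),
      Wv = .glorot(D, D), bv = numeric(D),
      Wo = .glorot(D, D), bo = numeric(D),
      g1 = rep(1, D), be1 = numeric(D),
      W1 = .glorot(D, Dff), c1 = numeric(Dff),
      W2 = .glorot(Dff, D), c2 = numeric(D),
      g2 = rep(1, D), be2 = numeric(D)
    )
  })
  list(
    e_cls = stats::rnorm(D, 0, 0.02),
    pos = matrix(stats::rnorm(cfg$max_T * D, 0, 0.02), cfg$max_T, D),
    layers = layers,
    P1 = .glorot(D, E), c1p = numeric(E),
    P2 = .glorot(E, E), c2p = numeric(E),
    proto = matrix(stats::rnorm(nCategories * E, 0, 1 / sqrt(E)),
                   nCategories, E)
  )
}

.zeroLike <- function(x) rapply(x, function(v) v * 0, how = "replace")

.accumulate <- function(a, b) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- .accumulate(a[[nm]], b[[nm]])
    a
  } else {
    a + b
  }
}

.sgdStep <- function(p, g, lr) {
  if (is.list(p)) {
    for (nm in seq_along(p)) p[[nm]] <- .sgdStep(p[[nm]], g[[nm]], lr)
    p
  } else {
    p - lr * g
  }
}

.LN_EPS <- 1e-5

# Row-wise layer normalization. Returns the output and the quantities
# needed for the backward pass.
.layerNormFwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  invsig <- 1 / sqrt(rowMeans(xc^2) + .LN_EPS)
  xhat <- xc * invsig
  Y <- .addBias(xhat * matrix(g, nrow(X), length(g), byrow = TRUE), b)
  list(Y = Y, xhat = xhat, invsig = invsig)
}

.layerNormBwd <- function(dY, cache, g) {
  G <- matrix(g, nrow(dY), length(g), byrow = TRUE)
  dxhat <- dY * G
  dg <- colSums(dY * cache$xhat)
  db <- colSums(dY)
  dx <- cache$invsig *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, dg = dg, db = db)
}

# Forward pass of the masked transformer encoder for one modality
# stream. X is the T x D frame-feature matrix (padded rows all-zero),
# mask marks valid frames. Returns the cls representation at the final
# layer plus, when wanted, the cache for the backward pass and the
# cls-row attention of the final layer.
.encoderForward <- function(X, mask, params, cfg, train = FALSE,
                            keepCache = FALSE) {
  Tn <- nrow(X)
  if (Tn > cfg$max_T)
    stop(sprintf("sequence of %d frames exceeds positional capacity max_T=%d",
                 Tn, cfg$max_T))
  if (!any(mask)) stop("sequence has no valid frames")
  if (!cfg$use_self_attention) {
    h <- colMeans(X[mask, , drop = FALSE])
    return(list(h = h, cache = NULL, clsAttention = NULL))
  }
  Xp <- X
  if (cfg$use_positional)
    Xp <- Xp + params$pos[seq_len(Tn), , drop = FALSE]
  Z <- rbind(params$e_cls, Xp)
  km <- c(TRUE, mask)
  D <- cfg$D; H <- cfg$n_heads; dh <- D / H
  p <- if (train) cfg$dropout else 0
  caches <- if (keepCache) vector("list", cfg$n_layers) else NULL
  clsAttn <- NULL
  for (l in seq_len(cfg$n_layers)) {
    L <- params$layers[[l]]
    Q <- .addBias(Z %*% L$Wq, L$bq)
    K <- .addBias(Z %*% L$Wk, L$bk)
    V <- .addBias(Z %*% L$Wv, L$bv)
    O <- matrix(0, Tn + 1L, D)
    Pheads <- vector("list", H)
    for (h in seq_len(H)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      S <- (Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE])) / sqrt(dh)
      Pa <- .softmaxRows(S, keep = km)
      Pheads[[h]] <- Pa
      O[, idx] <- Pa %*% V[, idx, drop = FALSE]
    }
    M <- .addBias(O %*% L$Wo, L$bo)
    dm1 <- NULL
    if (p > 0) {
      dm1 <- matrix(stats::rbinom(length(M), 1L, 1 - p), nrow(M)) / (1 - p)
      M <- M * dm1
    }
    ln1 <- .layerNormFwd(Z + M, L$g1, L$be1)
    X1 <- ln1$Y
    Hpre <- .addBias(X1 %*% L$W1, L$c1)
    A <- pmax(Hpre, 0)
    Fo <- .addBias(A %*% L$W2, L$c2)
    dm2 <- NULL
    if (p > 0) {
      dm2 <- matrix(stats::rbinom(length(Fo), 1L, 1 - p), nrow(Fo)) / (1 - p)
      Fo <- Fo * dm2
    }
    ln2 <- .layerNormFwd(X1 + Fo, L$g2, L$be2)
    if (keepCache) {
      caches[[l]] <- list(Z = Z, Q = Q, K = K, V = V, Pheads = Pheads, O = O,
                          dm1 = dm1, ln1 = ln1, X1 = X1, Hpre = Hpre, A = A,
                          dm2 = dm2, ln2 = ln2)
    }
    if (l == cfg$n_layers) {
      # cls-row attention, averaged over heads (explanation signal)
      W <- Reduce(`+`, lapply(Pheads, function(Pa) Pa[1L, ])) / H
      clsAttn <- W
    }
    Z <- ln2$Y
  }
  list(h = Z[1L, ], cache = list(layers = caches, km = km, Tn = Tn),
       clsAttention = clsAttn)
}

# Backward pass matching .encoderForward. dh is the gradient w.r.t. the
# final cls representation. Returns gradients for the encoder-owned
# parameters plus dX (gradient w.r.t. the input frame features, used
# only by tests) accumulated into `grads` (a zero-initialized structure
# sharing the shape of params).
.encoderBackward <- function(dh, cache, params, cfg, grads) {
  Tn <- cache$Tn
  km <- cache$km
  D <- cfg$D; H <- cfg$n_heads; dh_ <- D / H
  dZ <- matrix(0, Tn + 1L, D)
  dZ[1L, ] <- dh
  for (l in rev(seq_len(cfg$n_layers))) {
    L <- params$layers[[l]]
    cc <- cache$layers[[l]]
    ln2b <- .layerNormBwd(dZ, cc$ln2, L$g2)
    grads$layers[[l]]$g2 <- grads$layers[[l]]$g2 + ln2b$dg
    grads$layers[[l]]$be2 <- grads$layers[[l]]$be2 + ln2b$db
    dR2 <- ln2b$dx
    dFo <- dR2
    if (!is.null(cc$dm2)) dFo <- dFo * cc$dm2
    grads$layers[[l]]$W2 <- grads$layers[[l]]$W2 + t(cc$A) %*% dFo
    grads$layers[[l]]$c2 <- grads$layers[[l]]$c2 + colSums(dFo)
    dA <- dFo %*% t(L$W2)
    dHpre <- dA * (cc$Hpre > 0)
    grads$layers[[l]]$W1 <- grads$layers[[l]]$W1 + t(cc$X1) %*% dHpre
    grads$layers[[l]]$c1 <- grads$layers[[l]]$c1 + colSums(dHpre)
    dX1 <- dR2 + dHpre %*% t(L$W1)
    ln1b <- .layerNormBwd(dX1, cc$ln1, L$g1)
    grads$layers[[l]]$g1 <- grads$layers[[l]]$g1 + ln1b$dg
    grads$layers[[l]]$be1 <- grads$layers[[l]]$be1 + ln1b$db
    dR1 <- ln1b$dx
    dM <- dR1
    if (!is.null(cc$dm1)) dM <- dM * cc$dm1
    grads$layers[[l]]$Wo <- grads$layers[[l]]$Wo + t(cc$O) %*% dM
    grads$layers[[l]]$bo <- grads$layers[[l]]$bo + colSums(dM)
    dO <- dM %*% t(L$Wo)
    dQ <- matrix(0, Tn + 1L, D)
    dK <- matrix(0, Tn + 1L, D)
    dV <- matrix(0, Tn + 1L, D)
    for (h in seq_len(H)) {
      idx <- ((h - 1L) * dh_ + 1L):(h * dh_)
      Pa <- cc$Pheads[[h]]
      dOh <- dO[, idx, drop = FALSE]
      dPa <- dOh %*% t(cc$V[, idx, drop = FALSE])
      dV[, idx] <- t(Pa) %*% dOh
      dS <- Pa * (dPa - rowSums(dPa * Pa))
      dQ[, idx] <- (dS %*% cc$K[, idx, drop = FALSE]) / sqrt(dh_)
      dK[, idx] <- (t(dS) %*% cc$Q[, idx, drop = FALSE]) / sqrt(dh_)
    }
    grads$layers[[l]]$Wq <- grads$layers[[l]]$Wq + t(cc$Z) %*% dQ
    grads$layers[[l]]$bq <- grads$layers[[l]]$bq + colSums(dQ)
    grads$layers[[l]]$Wk <- grads$layers[[l]]$Wk + t(cc$Z) %*% dK
    grads$layers[[l]]$bk <- grads$layers[[l]]$bk + colSums(dK)
    grads$layers[[l]]$Wv <- grads$layers[[l]]$Wv + t(cc$Z) %*% dV
    grads$layers[[l]]$bv <- grads$layers[[l]]$bv + colSums(dV)
    dZ <- dR1 + dQ %*% t(L$Wq) + dK %*% t(L$Wk) + dV %*% t(L$Wv)
  }
  grads$e_cls <- grads$e_cls + dZ[1L, ]
  if (cfg$use_positional) {
    grads$pos[seq_len(Tn), ] <- grads$pos[seq_len(Tn), , drop = FALSE] +
      dZ[-1L, , drop = FALSE]
  }
  list(grads = grads, dX = dZ[-1L, , drop = FALSE])
}
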