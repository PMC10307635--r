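# Internal numerical helpers shared across modules.

# Row-wise softmax of a score matrix with an optional key mask.
# Masked columns receive zero probability; every row must retain at least
# one unmasked column.
.softmaxRows <- function(S, keep = NULL) {
  if (!is.null(keep)) S[, !keep] <- -Inf
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

.softmaxVec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Broadcast a bias vector over the rows of a matrix.
.addBias <- function(M, b) {
  M + matrix(b, nrow(M), length(b), byrow = TRUE)
}

.cosine <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero-norm vector")
  sum(u * v) / (nu * nv)
}

# Shannon entropy in nats with the 0*log(0) = 0 convention.
.entropyNat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

.isCount <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

.stopifnotFinite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("%s contains non-finite values", what))
}

# Deterministic small-integer seed derived from a base seed and an offset,
# kept within the 32-bit integer range expected by set.seed().
.deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(offset)) %% 2147483647)
}
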