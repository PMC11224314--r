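# Shared fixtures and independent oracles for the suite. Everything is
# generated in code; caches avoid re-training across tests in one run.

# tiny architecture used by most network/training tests
tinyAttention <- function(...) {
  attentionConfig(nHeads = 2L, dModel = 16L, dQ = 8L, dK = 8L, dV = 8L, ...)
}

tinyModelConfig <- function(nClasses = 3L, ...) {
  modelConfig(nClasses = nClasses, attention = tinyAttention(),
              lstmHidden = 16L, mlpOut = 16L, ...)
}

# the reduced learnable configuration (T=20, C=8, N=3, dModel=32, 2 heads)
reducedModelConfig <- function(...) {
  modelConfig(nClasses = 3L,
              attention = attentionConfig(nHeads = 2L, dModel = 32L,
                                          dQ = 16L, dK = 16L, dV = 16L, ...),
              lstmHidden = 32L, mlpOut = 32L)
}

# high-SNR synthetic conditions for the reduced geometry: narrow bumps,
# mild jitter, low noise -- cleanly separable by a nearest-template rule
highSnrSpec <- function(seed = 7L, trialsPerClass = 20L) {
  syntheticSpec(tSteps = 20L, nChannels = 8L, nClasses = 3L,
                trialsPerClass = trialsPerClass, bumpsPerClass = 3L,
                bumpTimeWidth = 2, bumpChannelSpan = 1, timeJitterSd = 0.3,
                noiseSd = 0.05, seed = seed)
}

tinySpec <- function(seed = 11L, nClasses = 3L, trialsPerClass = 10L) {
  syntheticSpec(tSteps = 10L, nChannels = 6L, nClasses = nClasses,
                trialsPerClass = trialsPerClass, bumpsPerClass = 2L,
                bumpTimeWidth = 1, bumpChannelSpan = 0.8, timeJitterSd = 0.3,
                noiseSd = 0.05, seed = seed)
}

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- force(expr)
  .fixtureCache[[key]]
}

highSnrDataset <- function() cached("highSnr", generateDataset(highSnrSpec()))
tinyDataset <- function() cached("tiny", generateDataset(tinySpec()))

# ---------------------------------------------------------------------------
# Independent attention oracles: explicit element-wise loops, no shared code
# with the package implementation.

naiveSoftmaxRow <- function(x) {
  m <- max(x)
  e <- exp(x - m)
  e / sum(e)
}

naiveAttentionOracle <- function(Q, K, V, B = NULL) {
  lq <- nrow(Q); lk <- nrow(K); dv <- ncol(V)
  out <- matrix(0, lq, dv)
  for (i in seq_len(lq)) {
    scores <- numeric(lk)
    for (j in seq_len(lk)) {
      s <- 0
      for (d in seq_len(ncol(Q))) s <- s + Q[i, d] * K[j, d]
      scores[j] <- s / sqrt(ncol(K)) + if (is.null(B)) 0 else B[i, j]
    }
    w <- naiveSoftmaxRow(scores)
    for (d in seq_len(dv)) out[i, d] <- sum(w * V[, d])
  }
  out
}

naiveMultiHeadOracle <- function(querySeq, kvSeq, cfg, weights,
                                 biasTable = NULL) {
  pieces <- vector("list", cfg@nHeads)
  for (h in seq_len(cfg@nHeads)) {
    B <- NULL
    if (!is.null(biasTable)) {
      L <- (ncol(biasTable) + 1L) %/% 2L
      B <- matrix(0, nrow(querySeq), nrow(kvSeq))
      for (i in seq_len(nrow(querySeq)))
        for (j in seq_len(nrow(kvSeq)))
          B[i, j] <- biasTable[h, i - j + L]
    }
    pieces[[h]] <- naiveAttentionOracle(querySeq %*% weights$Wq[[h]],
                                        kvSeq %*% weights$Wk[[h]],
                                        kvSeq %*% weights$Wv[[h]], B)
  }
  do.call(cbind, pieces)
}

# central finite-difference gradient of a scalar function of a matrix
numericalGradient <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

referenceCsv <- function(name) {
  path <- system.file("extdata", name, package = "tscanet")
  if (!nzchar(path)) path <- file.path("../../inst/extdata", name)
  read.csv(path, stringsAsFactors = FALSE)
}
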