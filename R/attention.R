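# Position-bias-aware scaled dot-product multi-head attention.
#
# These are the plain-matrix reference operations; the trainable network
# builds the same computation on the autodiff tape (R/model.R) and the test
# suite asserts the two agree on identical weights.

#' Scaled dot-product attention with an additive score bias
#'
#' Computes `softmax(Q K' / sqrt(d_k) + B) V` row-wise, the single-head
#' attention primitive. The softmax subtracts the per-row maximum before
#' exponentiation, so arbitrarily large bias entries are safe.
#'
#' @param Q query matrix, `len_q x d_k`.
#' @param K key matrix, `len_k x d_k`.
#' @param V value matrix, `len_k x d_v`.
#' @param B additive score bias: a `len_q x len_k` matrix, a scalar, or
#'   NULL (treated as zero).
#' @return `len_q x d_v` matrix; the attention weights are attached as
#'   attribute `"weights"` (each row sums to 1).
#' @examples
#' Q <- matrix(rnorm(4), 2, 2); K <- matrix(rnorm(6), 3, 2)
#' V <- matrix(rnorm(6), 3, 2)
#' out <- scaledDotAttention(Q, K, V)
#' rowSums(attr(out, "weights"))   # all 1
#' @export
scaledDotAttention <- function(Q, K, V, B = NULL) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) {
    stop(sprintf("shape error: Q has inner dim %d but K has inner dim %d",
                 ncol(Q), ncol(K)))
  }
  if (nrow(K) != nrow(V)) {
    stop(sprintf("shape error: K has %d rows but V has %d rows",
                 nrow(K), nrow(V)))
  }
  scores <- tcrossprod(Q, K) / sqrt(ncol(K))
  if (!is.null(B)) {
    if (is.matrix(B) && (nrow(B) != nrow(Q) || ncol(B) != nrow(K))) {
      stop(sprintf("shape error: bias is %dx%d, expected %dx%d",
                   nrow(B), ncol(B), nrow(Q), nrow(K)))
    }
    scores <- scores + B
  }
  w <- softmaxRows(scores)
  out <- w %*% V
  attr(out, "weights") <- w
  out
}

#' Initialize multi-head attention projection weights
#'
#' Draws per-head query/key/value projection matrices
#' (`dModel x dQ/dK/dV`) with scaled Gaussian entries.
#'
#' @param cfg an [AttentionConfig-class].
#' @param seed integer seed.
#' @return list with elements `Wq`, `Wk`, `Wv`, each a list of `nHeads`
#'   matrices.
#' @export
initAttentionWeights <- function(cfg, seed = 1L) {
  withSeed(seed, {
    d <- cfg@dModel
    mk <- function(out) lapply(seq_len(cfg@nHeads), function(h)
      matrix(stats::rnorm(d * out, sd = 1 / sqrt(d)), d, out))
    list(Wq = mk(cfg@dQ), Wk = mk(cfg@dK), Wv = mk(cfg@dV))
  })
}

#' Multi-head attention over two sequences
#'
#' Projects the query sequence and the key/value sequence into each head's
#' query/key/value spaces, applies [scaledDotAttention()] per head (with the
#' head's resolved position bias, if any), and concatenates the head
#' outputs. Self-attention is the `kvSeq = querySeq` case; cross-attention
#' passes a different key/value source.
#'
#' @param querySeq `len_q x dModel` matrix.
#' @param kvSeq `len_k x dModel` matrix.
#' @param cfg an [AttentionConfig-class].
#' @param weights projections from [initAttentionWeights()] (or trained
#'   values of the same shape).
#' @param biasTable optional `nHeads x (2 L - 1)` relative-bias table; its
#'   resolved `len_q x len_k` matrix is added to each head's scores.
#'   Requires `len_q == len_k`.
#' @return `len_q x (nHeads * dV)` matrix.
#' @export
multiHeadAttention <- function(querySeq, kvSeq, cfg, weights,
                               biasTable = NULL) {
  querySeq <- as.matrix(querySeq); kvSeq <- as.matrix(kvSeq)
  if (ncol(querySeq) != cfg@dModel || ncol(kvSeq) != cfg@dModel) {
    stop(sprintf("shape error: query width %d / kv width %d, expected dModel %d",
                 ncol(querySeq), ncol(kvSeq), cfg@dModel))
  }
  heads <- lapply(seq_len(cfg@nHeads), function(h) {
    B <- if (!is.null(biasTable))
      resolvePositionBias(biasTable, nrow(querySeq), nrow(kvSeq), h)
    scaledDotAttention(querySeq %*% weights$Wq[[h]],
                       kvSeq %*% weights$Wk[[h]],
                       kvSeq %*% weights$Wv[[h]], B)
  })
  do.call(cbind, lapply(heads, function(x) { attr(x, "weights") <- NULL; x }))
}

#' Resolve a relative-position bias table into a score-bias matrix
#'
#' Entry `(i, j)` of the resolved matrix is the table entry for offset
#' `i - j`, i.e. `biasTable[h, i - j + L - 1 + 1]` for a table covering
#' offsets `-(L-1) .. L-1`. The result is constant along diagonals
#' (Toeplitz) by construction.
#'
#' @param biasTable `nHeads x (2 L - 1)` matrix of trainable biases.
#' @param lenQ,lenK query/key lengths; must be equal and at most `L`.
#' @param head which head's row to resolve.
#' @return `lenQ x lenK` matrix.
#' @export
resolvePositionBias <- function(biasTable, lenQ, lenK, head = 1L) {
  if (lenQ != lenK) {
    stop("relative position bias requires equal query and key lengths ",
         "(got ", lenQ, " and ", lenK, ")")
  }
  L <- (ncol(biasTable) + 1L) %/% 2L
  if (lenQ > L) {
    stop(sprintf("bias table covers length %d but sequence has length %d",
                 L, lenQ))
  }
  idx <- relativeBiasIndex(lenQ, lenK, L)
  matrix(biasTable[head, ][idx], lenQ, lenK)
}

# column index into a length-(2L-1) offset table for each (i, j):
# offset i - j mapped to i - j + L
relativeBiasIndex <- function(lenQ, lenK, L) {
  outer(seq_len(lenQ), seq_len(lenK), function(i, j) i - j + L)
}

#' Build the position treatment for a sequence
#'
#' The four variants act at different points of the computation:
#' `"relative"` contributes a trainable additive bias to the attention
#' scores (resolved from an offset-indexed table, one row per head);
#' `"absolute"` adds a trainable per-position vector to the input sequence;
#' `"sincos"` adds the fixed interleaved sine/cosine schedule; `"none"`
#' contributes nothing.
#'
#' @param kind one of `"relative"`, `"absolute"`, `"sincos"`, `"none"`.
#' @param seqLen sequence length (>= 1).
#' @param cfg an [AttentionConfig-class].
#' @param seed seed for the trainable initializations.
#' @return list with `inputAdditive` (`seqLen x dModel` matrix, zero unless
#'   the variant acts on the input) and `biasTable` (`nHeads x (2 seqLen - 1)`
#'   matrix for `"relative"`, otherwise NULL).
#' @export
buildPositionTreatment <- function(kind, seqLen, cfg, seed = 1L) {
  if (length(kind) != 1L || !kind %in% positionKinds) {
    stop("unknown position kind ", deparse(kind), "; valid kinds are: ",
         paste(positionKinds, collapse = ", "))
  }
  stopifnot(seqLen >= 1)
  zero <- matrix(0, seqLen, cfg@dModel)
  switch(kind,
    relative = list(
      inputAdditive = zero,
      biasTable = withSeed(seed, matrix(
        stats::rnorm(cfg@nHeads * (2L * seqLen - 1L), sd = 0.02),
        cfg@nHeads, 2L * seqLen - 1L))),
    absolute = list(
      inputAdditive = withSeed(seed, matrix(
        stats::rnorm(seqLen * cfg@dModel, sd = 0.02), seqLen, cfg@dModel)),
      biasTable = NULL),
    sincos = list(inputAdditive = sincosEmbedding(seqLen, cfg@dModel),
                  biasTable = NULL),
    none = list(inputAdditive = zero, biasTable = NULL))
}

#' Fixed sinusoidal position embedding
#'
#' Interleaved schedule: column `2i-1` is `sin(pos / 10000^(2(i-1)/d))` and
#' column `2i` the matching cosine, with positions counted from 0.
#'
#' @param seqLen number of positions.
#' @param dModel embedding width (even widths give exact sin/cos pairs).
#' @return `seqLen x dModel` matrix.
#' @export
sincosEmbedding <- function(seqLen, dModel) {
  pos <- seq_len(seqLen) - 1
  out <- matrix(0, seqLen, dModel)
  for (i in seq_len(ceiling(dModel / 2))) {
    freq <- 1 / 10000^((2 * (i - 1)) / dModel)
    out[, 2L * i - 1L] <- sin(pos * freq)
    if (2L * i <= dModel) out[, 2L * i] <- cos(pos * freq)
  }
  out
}
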