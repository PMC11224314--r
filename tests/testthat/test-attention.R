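# Attention core: scaled dot-product with additive score bias, multi-head
# projection/concatenation, and the four position treatments.

test_that("attention weights are a convex combination and rows sum to one", {
  set.seed(1)
  Q <- matrix(rnorm(8), 4, 2); K <- matrix(rnorm(10), 5, 2)
  V <- matrix(rnorm(15), 5, 3)
  out <- scaledDotAttention(Q, K, V)
  w <- attr(out, "weights")
  expect_equal(rowSums(w), rep(1, 4), tolerance = 1e-6)
  expect_true(all(w >= 0))
  # convexity: outputs lie inside the per-column range of V
  for (d in 1:3) {
    expect_true(all(out[, d] >= min(V[, d]) - 1e-12))
    expect_true(all(out[, d] <= max(V[, d]) + 1e-12))
  }
})

test_that("a single key/value row is returned exactly", {
  Q <- matrix(c(0.3, -2, 5, 0.1), 2, 2)
  K <- matrix(c(1, 2), 1, 2)
  V <- matrix(c(3.5, -1.25), 1, 2)
  out <- scaledDotAttention(Q, K, V, B = matrix(0, 2, 1))
  expect_identical(out[1, ], V[1, ])
  expect_identical(out[2, ], V[1, ])
})

test_that("zero bias reproduces the unbiased attention bitwise", {
  set.seed(2)
  Q <- matrix(rnorm(6), 3, 2); K <- matrix(rnorm(8), 4, 2)
  V <- matrix(rnorm(12), 4, 3)
  a <- scaledDotAttention(Q, K, V)
  b <- scaledDotAttention(Q, K, V, B = matrix(0, 3, 4))
  expect_identical(unclass(a), unclass(b))
})

test_that("a large bias entry routes all attention to the biased key", {
  Q <- matrix(c(1, 0, 0, 1), 2, 2)
  K <- matrix(c(1, 2, 0, 0, 1, 2), 3, 2)
  V <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  B <- matrix(0, 2, 3); B[1, 2] <- 1e4
  out <- scaledDotAttention(Q, K, V, B)
  expect_equal(out[1, ], V[2, ], tolerance = 1e-3)
  expect_equal(out, naiveAttentionOracle(Q, K, V, B),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("shape errors name the mismatched operands", {
  expect_error(scaledDotAttention(matrix(0, 2, 3), matrix(0, 2, 2),
                                  matrix(0, 2, 2)),
               "Q has inner dim 3 but K has inner dim 2")
  expect_error(scaledDotAttention(matrix(0, 2, 2), matrix(0, 3, 2),
                                  matrix(0, 4, 2)),
               "K has 3 rows but V has 4 rows")
  expect_error(scaledDotAttention(matrix(0, 2, 2), matrix(0, 3, 2),
                                  matrix(0, 3, 2), B = matrix(0, 2, 2)),
               "bias is 2x2, expected 2x3")
})

test_that("multi-head attention matches a naive per-head loop oracle", {
  # all sequence lengths up to 6 and widths up to 8
  for (lq in c(1L, 3L, 6L)) {
    for (lk in c(1L, 4L, 6L)) {
      for (d in c(2L, 8L)) {
        cfg <- attentionConfig(nHeads = 2L, dModel = d, dQ = 4L, dK = 4L,
                               dV = 3L, positionKind = "none")
        w <- initAttentionWeights(cfg, seed = lq * 100L + lk * 10L + d)
        set.seed(lq + lk + d)
        qs <- matrix(rnorm(lq * d), lq, d)
        kv <- matrix(rnorm(lk * d), lk, d)
        got <- multiHeadAttention(qs, kv, cfg, w)
        expect_equal(dim(got), c(lq, 2L * 3L))
        expect_equal(got, naiveMultiHeadOracle(qs, kv, cfg, w),
                     tolerance = 1e-5)
      }
    }
  }
})

test_that("multi-head with relative bias matches the oracle", {
  cfg <- attentionConfig(nHeads = 3L, dModel = 6L, dQ = 4L, dK = 4L, dV = 2L)
  w <- initAttentionWeights(cfg, seed = 9L)
  pt <- buildPositionTreatment("relative", 5L, cfg, seed = 9L)
  set.seed(10)
  x <- matrix(rnorm(30), 5, 6)
  got <- multiHeadAttention(x, x, cfg, w, biasTable = pt$biasTable)
  expect_equal(got, naiveMultiHeadOracle(x, x, cfg, w, pt$biasTable),
               tolerance = 1e-5)
})

test_that("identity single-head projection reduces to plain attention", {
  d <- 4L
  cfg <- attentionConfig(nHeads = 1L, dModel = d, dQ = d, dK = d, dV = d,
                         positionKind = "none")
  w <- list(Wq = list(diag(d)), Wk = list(diag(d)), Wv = list(diag(d)))
  set.seed(3)
  qs <- matrix(rnorm(3 * d), 3, d); kv <- matrix(rnorm(5 * d), 5, d)
  mh <- multiHeadAttention(qs, kv, cfg, w)
  plain <- scaledDotAttention(qs, kv, kv)
  expect_equal(mh, unclass(plain), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("position treatments have the required structure", {
  cfg <- attentionConfig(nHeads = 2L, dModel = 8L, dQ = 4L, dK = 4L, dV = 4L)
  rel <- buildPositionTreatment("relative", 5L, cfg)
  expect_true(all(rel$inputAdditive == 0))
  expect_equal(dim(rel$biasTable), c(2L, 9L))
  abs_ <- buildPositionTreatment("absolute", 5L, cfg)
  expect_null(abs_$biasTable)
  expect_false(all(abs_$inputAdditive == 0))
  none <- buildPositionTreatment("none", 5L, cfg)
  expect_true(all(none$inputAdditive == 0) && is.null(none$biasTable))
  sc <- buildPositionTreatment("sincos", 4L, cfg)
  # position 0: sin(0) = 0 and cos(0) = 1 interleaved
  expect_equal(sc$inputAdditive[1, ], rep(c(0, 1), 4))
  expect_error(buildPositionTreatment("fourier", 5L, cfg),
               "relative, absolute, sincos, none")
})

test_that("resolved relative bias matrices are Toeplitz for all tested lengths", {
  cfg <- attentionConfig(nHeads = 2L, dModel = 8L, dQ = 4L, dK = 4L, dV = 4L)
  for (L in 2:7) {
    pt <- buildPositionTreatment("relative", L, cfg, seed = L)
    for (h in 1:2) {
      B <- resolvePositionBias(pt$biasTable, L, L, h)
      for (i in seq_len(L)) for (j in seq_len(L)) {
        expect_identical(B[i, j], pt$biasTable[h, i - j + L])
      }
      # constant along every diagonal
      for (off in -(L - 1):(L - 1)) {
        diagVals <- B[cbind(seq_len(L), seq_len(L) - off)[
          seq_len(L) - off >= 1 & seq_len(L) - off <= L, , drop = FALSE]]
        expect_lt(max(diagVals) - min(diagVals), 1e-15)
      }
    }
  }
})

test_that("relative bias rejects unequal query/key lengths", {
  cfg <- attentionConfig(nHeads = 1L, dModel = 4L, dQ = 2L, dK = 2L, dV = 2L)
  pt <- buildPositionTreatment("relative", 5L, cfg)
  expect_error(resolvePositionBias(pt$biasTable, 4, 5), "equal query and key")
})
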