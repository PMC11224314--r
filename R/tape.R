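# Reverse-mode automatic differentiation on dense matrices.
#
# A tape is an environment accumulating nodes in topological order; every
# node holds a numeric matrix `value`, the indices of its parent nodes, and a
# vector-Jacobian product closure mapping the gradient at the node to the
# gradients of its parents. backpropagation is a single reverse sweep.
# Parameters are leaf nodes tagged with a name so their gradients can be
# collected into a flat list for the optimizer.
#
# Only the operations the network needs are implemented; each op's vjp is
# verified against central finite differences in the test suite.

tapeNew <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tapePush <- function(tp, value, parents = integer(0), vjp = NULL,
                     param = NA_character_) {
  # force before reserving a slot: evaluating `value`/`parents` may itself
  # push nodes onto the tape
  force(value); force(parents); force(vjp); force(param)
  n <- tp$n + 1L
  if (n > length(tp$nodes)) {
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  }
  tp$nodes[[n]] <- list(value = value, parents = parents, vjp = vjp,
                        param = param)
  tp$n <- n
  n
}

tapeValue <- function(tp, id) {
  force(id)   # `id` may be an op call that itself grows the tape
  tp$nodes[[id]]$value
}

# Leaves ---------------------------------------------------------------------

agConst <- function(tp, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  tapePush(tp, x)
}

agParam <- function(tp, x, name) {
  stopifnot(is.matrix(x), is.character(name))
  tapePush(tp, x, param = name)
}

# Binary / unary elementwise --------------------------------------------------

agAdd <- function(tp, a, b) {
  tapePush(tp, tapeValue(tp, a) + tapeValue(tp, b), c(a, b),
           function(g) list(g, g))
}

agSub <- function(tp, a, b) {
  tapePush(tp, tapeValue(tp, a) - tapeValue(tp, b), c(a, b),
           function(g) list(g, -g))
}

agMul <- function(tp, a, b) {
  va <- tapeValue(tp, a); vb <- tapeValue(tp, b)
  tapePush(tp, va * vb, c(a, b),
           function(g) list(g * vb, g * va))
}

agScale <- function(tp, a, s) {
  tapePush(tp, tapeValue(tp, a) * s, a, function(g) list(g * s))
}

agUnary <- function(tp, a, f, df) {
  va <- tapeValue(tp, a)
  y <- f(va)
  tapePush(tp, y, a, function(g) list(g * df(va, y)))
}

agSigmoid <- function(tp, a) {
  agUnary(tp, a, function(x) 1 / (1 + exp(-x)), function(x, y) y * (1 - y))
}

agTanh <- function(tp, a) {
  agUnary(tp, a, tanh, function(x, y) 1 - y * y)
}

# exact GELU: x * Phi(x)
agGelu <- function(tp, a) {
  agUnary(tp, a,
          function(x) x * stats::pnorm(x),
          function(x, y) stats::pnorm(x) + x * stats::dnorm(x))
}

agSqrt <- function(tp, a) {
  agUnary(tp, a, sqrt, function(x, y) 0.5 / y)
}

# Matrix products and reshaping ----------------------------------------------

agMatmul <- function(tp, a, b) {
  va <- tapeValue(tp, a); vb <- tapeValue(tp, b)
  if (ncol(va) != nrow(vb)) {
    stop("matmul shape mismatch: ", nrow(va), "x", ncol(va), " %*% ",
         nrow(vb), "x", ncol(vb))
  }
  tapePush(tp, va %*% vb, c(a, b),
           function(g) list(g %*% t(vb), crossprod(va, g)))
}

agTranspose <- function(tp, a) {
  tapePush(tp, t(tapeValue(tp, a)), a, function(g) list(t(g)))
}

agRows <- function(tp, a, idx) {
  va <- tapeValue(tp, a)
  nr <- nrow(va)
  tapePush(tp, va[idx, , drop = FALSE], a, function(g) {
    d <- matrix(0, nr, ncol(g))
    agg <- rowsum(g, group = idx)
    d[as.integer(rownames(agg)), ] <- agg
    list(d)
  })
}

agCols <- function(tp, a, idx) {
  va <- tapeValue(tp, a)
  nc <- ncol(va)
  tapePush(tp, va[, idx, drop = FALSE], a, function(g) {
    d <- matrix(0, nrow(g), nc)
    agg <- rowsum(t(g), group = idx)
    d[, as.integer(rownames(agg))] <- t(agg)
    list(d)
  })
}

agRbind <- function(tp, ids) {
  vals <- lapply(ids, tapeValue, tp = tp)
  nr <- vapply(vals, nrow, 1L)
  ends <- cumsum(nr)
  starts <- ends - nr + 1L
  tapePush(tp, do.call(rbind, vals), as.integer(ids), function(g) {
    lapply(seq_along(ids), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

agCbind <- function(tp, ids) {
  vals <- lapply(ids, tapeValue, tp = tp)
  nc <- vapply(vals, ncol, 1L)
  ends <- cumsum(nc)
  starts <- ends - nc + 1L
  tapePush(tp, do.call(cbind, vals), as.integer(ids), function(g) {
    lapply(seq_along(ids), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

# Gather arbitrary elements of a parameter matrix into a new matrix shape;
# used to resolve the relative-position bias table into a len_q x len_k
# matrix. `idx` is a matrix of linear indices into `a`.
agGather <- function(tp, a, idx) {
  va <- tapeValue(tp, a)
  dims <- dim(va)
  tapePush(tp, matrix(va[idx], nrow(idx), ncol(idx)), a, function(g) {
    d <- matrix(0, dims[1L], dims[2L])
    acc <- rowsum(as.vector(g), group = as.vector(idx))
    d[as.integer(rownames(acc))] <- acc
    list(d)
  })
}

# Row-broadcast ops: `r` is a 1 x d node broadcast over the rows of `a`.

agBcastAdd <- function(tp, a, r) {
  va <- tapeValue(tp, a); vr <- tapeValue(tp, r)
  stopifnot(nrow(vr) == 1L, ncol(va) == ncol(vr))
  tapePush(tp, sweep(va, 2L, as.vector(vr), "+"), c(a, r),
           function(g) list(g, matrix(colSums(g), 1L)))
}

agBcastMul <- function(tp, a, r) {
  va <- tapeValue(tp, a); vr <- tapeValue(tp, r)
  stopifnot(nrow(vr) == 1L, ncol(va) == ncol(vr))
  tapePush(tp, sweep(va, 2L, as.vector(vr), "*"), c(a, r),
           function(g) list(sweep(g, 2L, as.vector(vr), "*"),
                            matrix(colSums(g * va), 1L)))
}

# Column means: L x d -> 1 x d (global average pooling over the sequence axis)
agColMeans <- function(tp, a) {
  va <- tapeValue(tp, a)
  nr <- nrow(va)
  tapePush(tp, matrix(colMeans(va), 1L), a,
           function(g) list(matrix(rep(g / nr, each = nr), nr)))
}

# Row-wise softmax with max-subtraction for stability.
agSoftmaxRows <- function(tp, a) {
  va <- tapeValue(tp, a)
  p <- softmaxRows(va)
  tapePush(tp, p, a, function(g) {
    list(p * (g - rowSums(g * p)))
  })
}

# Fused mean cross-entropy over logits: value is a 1x1 matrix holding
# -(1/B) sum_b log softmax(logits)[b, label_b]; gradient is the standard
# (softmax - onehot)/B, numerically safe for any logit magnitude.
agCrossEntropyLogits <- function(tp, logits, labels1) {
  z <- tapeValue(tp, logits)
  stopifnot(nrow(z) == length(labels1), all(labels1 >= 1L),
            all(labels1 <= ncol(z)))
  m <- apply(z, 1L, max)
  lse <- m + log(rowSums(exp(z - m)))
  picked <- z[cbind(seq_len(nrow(z)), labels1)]
  loss <- mean(lse - picked)
  b <- nrow(z)
  tapePush(tp, matrix(loss, 1L, 1L), logits, function(g) {
    p <- exp(z - lse)   # softmax rows
    p[cbind(seq_len(b), labels1)] <- p[cbind(seq_len(b), labels1)] - 1
    list(p * (as.numeric(g) / b))
  })
}

# Batch normalization over the rows of a (B*L) x d matrix, per feature
# column. In training mode the batch statistics are used and returned (for
# running-average updates); in eval mode the supplied moments are used.
agBatchNorm <- function(tp, a, gamma, beta, eps = 1e-5,
                        training = TRUE, runMean = NULL, runVar = NULL) {
  va <- tapeValue(tp, a)
  if (training) {
    mu <- colMeans(va)
    vv <- colMeans(sweep(va, 2L, mu, "-")^2)   # biased, as batch statistics
  } else {
    mu <- runMean
    vv <- runVar
  }
  inv <- 1 / sqrt(vv + eps)
  xhat <- sweep(sweep(va, 2L, mu, "-"), 2L, inv, "*")
  vg <- tapeValue(tp, gamma); vb <- tapeValue(tp, beta)
  out <- sweep(sweep(xhat, 2L, as.vector(vg), "*"), 2L, as.vector(vb), "+")
  n <- nrow(va)
  id <- tapePush(tp, out, c(a, gamma, beta), function(g) {
    dgamma <- matrix(colSums(g * xhat), 1L)
    dbeta <- matrix(colSums(g), 1L)
    gx <- sweep(g, 2L, as.vector(vg), "*")
    if (training) {
      # d/dx of (x - mean)/sd with batch statistics
      dx <- sweep(gx - matrix(rep(colMeans(gx), each = n), n) -
                    xhat * matrix(rep(colMeans(gx * xhat), each = n), n),
                  2L, inv, "*")
    } else {
      dx <- sweep(gx, 2L, inv, "*")
    }
    list(dx, dgamma, dbeta)
  })
  attr(id, "batchMean") <- mu
  attr(id, "batchVar") <- vv
  id
}

# Backward sweep --------------------------------------------------------------

# Returns a named list of gradients for every parameter leaf reached from
# `root` (a scalar node). Gradients for the same parameter name accumulate.
tapeBackward <- function(tp, root) {
  stopifnot(length(tapeValue(tp, root)) == 1L)
  grads <- vector("list", tp$n)
  grads[[root]] <- matrix(1, 1L, 1L)
  paramGrads <- list()
  for (i in seq(root, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    node <- tp$nodes[[i]]
    if (!is.na(node$param)) {
      nm <- node$param
      paramGrads[[nm]] <- if (is.null(paramGrads[[nm]])) g else
        paramGrads[[nm]] + g
    }
    if (length(node$parents)) {
      pg <- node$vjp(g)
      for (k in seq_along(node$parents)) {
        p <- node$parents[k]
        grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
      }
    }
    grads[i] <- list(NULL)
  }
  paramGrads
}

# Plain-matrix helpers shared with the non-autograd code paths ----------------

softmaxRows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

geluMat <- function(x) x * stats::pnorm(x)
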