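# The TSCA-Net architecture: a temporal-feature stream (linear embedding ->
# batch norm -> LSTM -> batch norm -> self-attention -> MLP), a
# spatial-feature stream (transposed trial -> embedding -> batch norm ->
# self-attention -> MLP), two temporal-spatial cross-attention blocks
# (channel sequence querying the temporal representation, and time sequence
# querying the spatial representation), and a pooled two-layer softmax
# classifier. All stages run on the autodiff tape so the same code path
# serves training and evaluation; evaluation uses running batch-norm moments
# and is a pure function of weights and input.
#
# Layout conventions: a batch of B trials is carried as a (B*L) x d matrix
# in batch-major order (trial b occupies rows (b-1)*L+1 .. b*L). Attention
# is computed per trial on row slices.

# ---------------------------------------------------------------------------
# Initialization

#' Initialize a TSCA-Net model
#'
#' Creates all trainable parameters for the configured architecture, bound
#' to a fixed trial geometry (the embedding maps fix the channel count and
#' time length they were trained for). Parameters exist only for enabled
#' components, so switching a toggle off strictly reduces the parameter
#' count.
#'
#' @param cfg a [ModelConfig-class].
#' @param tSteps,nChannels trial geometry the model is built for.
#' @param seed integer seed for weight initialization.
#' @return a model object (list with `cfg`, geometry, `params`, and
#'   batch-norm running moments).
#' @examples
#' m <- initModel(modelConfig(nClasses = 3,
#'          attention = attentionConfig(nHeads = 2, dModel = 16, dQ = 8,
#'                                      dK = 8, dV = 8),
#'          lstmHidden = 16, mlpOut = 16), tSteps = 10, nChannels = 6)
#' countParameters(m)
#' @export
initModel <- function(cfg, tSteps, nChannels, seed = 1L) {
  stopifnot(is(cfg, "ModelConfig"))
  validObject(cfg)
  a <- cfg@attention
  d <- a@dModel
  H <- cfg@lstmHidden
  Tn <- as.integer(tSteps); Cn <- as.integer(nChannels)
  tfOn <- cfg@useTfLstm || cfg@useTfTransformer

  needEmbT <- tfOn || cfg@useSingleC
  needEmbC <- cfg@useSf || cfg@useSingleT || (cfg@useSingleC && !cfg@useSf)

  params <- list()
  running <- list()
  withSeed(seed, {
    g <- function(nr, nc, sd = 1 / sqrt(nr)) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
    addBn <- function(name) {
      params[[paste0(name, ".gamma")]] <<- matrix(1, 1L, d)
      params[[paste0(name, ".beta")]] <<- matrix(0, 1L, d)
      running[[name]] <<- list(mean = rep(0, d), var = rep(1, d))
    }
    addMsa <- function(name) {
      for (h in seq_len(a@nHeads)) {
        params[[sprintf("%s.Wq%d", name, h)]] <<- g(d, a@dQ)
        params[[sprintf("%s.Wk%d", name, h)]] <<- g(d, a@dK)
        params[[sprintf("%s.Wv%d", name, h)]] <<- g(d, a@dV)
      }
    }
    addMlp <- function(name) {
      wide <- a@nHeads * a@dV
      params[[paste0(name, ".W1")]] <<- g(wide, d)
      params[[paste0(name, ".b1")]] <<- matrix(0, 1L, d)
      params[[paste0(name, ".W2")]] <<- g(d, d)
      params[[paste0(name, ".b2")]] <<- matrix(0, 1L, d)
    }
    addPos <- function(name, len) {
      if (a@positionKind == "relative") {
        params[[paste0(name, ".bias")]] <<-
          matrix(stats::rnorm(a@nHeads * (2L * len - 1L), sd = 0.02),
                 a@nHeads, 2L * len - 1L)
      } else if (a@positionKind == "absolute") {
        params[[paste0(name, ".pos")]] <<-
          matrix(stats::rnorm(len * d, sd = 0.02), len, d)
      }
    }

    if (needEmbT) {
      params[["embT.W"]] <- g(Cn, d)
      params[["embT.b"]] <- matrix(0, 1L, d)
    }
    if (needEmbC) {
      params[["embC.W"]] <- g(Tn, d)
      params[["embC.b"]] <- matrix(0, 1L, d)
    }
    if (tfOn) {
      addBn("tf.bn1")
      if (cfg@useTfLstm) {
        params[["tf.lstm.Wx"]] <- g(d, 4L * H)
        params[["tf.lstm.Wh"]] <- g(H, 4L * H)
        params[["tf.lstm.b"]] <- matrix(0, 1L, 4L * H)
        addBn("tf.bn2")
      }
      if (cfg@useTfTransformer) {
        addPos("tf", Tn)
        addMsa("tf.msa")
        addMlp("tf.mlp")
      }
    }
    if (cfg@useSf) {
      addBn("sf.bn")
      addPos("sf", Cn)
      addMsa("sf.msa")
      addMlp("sf.mlp")
    }
    if (cfg@useSingleT) {
      addMsa("ct.msa")
      addMlp("ct.mlp")
      if (a@crossPositionBias && a@positionKind == "relative" && Tn == Cn)
        addPos("ct", Cn)
    }
    if (cfg@useSingleC) {
      addMsa("cc.msa")
      addMlp("cc.mlp")
      if (a@crossPositionBias && a@positionKind == "relative" && Tn == Cn)
        addPos("cc", Tn)
    }
    params[["clf.W1"]] <- g(d, d)
    params[["clf.b1"]] <- matrix(0, 1L, d)
    params[["clf.W2"]] <- g(d, cfg@nClasses)
    params[["clf.b2"]] <- matrix(0, 1L, cfg@nClasses)
  })

  list(cfg = cfg, tSteps = Tn, nChannels = Cn, seed = as.integer(seed),
       params = params, running = running)
}

#' Count trainable parameters
#'
#' @param model a model from [initModel()].
#' @return total number of trainable scalar parameters.
#' @export
countParameters <- function(model) {
  sum(vapply(model$params, length, 1L))
}

# ---------------------------------------------------------------------------
# Forward pass

# Build the full forward computation for a batch of trials on a tape.
# Returns node ids for the logits and each stage, plus batch-norm batch
# statistics (training mode) for running-moment updates.
forwardCore <- function(model, batch, training = FALSE, tp = NULL) {
  cfg <- model$cfg
  a <- cfg@attention
  d <- a@dModel
  Tn <- model$tSteps; Cn <- model$nChannels
  B <- length(batch)
  tfOn <- cfg@useTfLstm || cfg@useTfTransformer
  if (is.null(tp)) tp <- tapeNew()

  for (i in seq_len(B)) {
    tr <- batch[[i]]
    if (!is.matrix(tr) || nrow(tr) != Tn || ncol(tr) != Cn) {
      stop(sprintf(
        "trial %d is %sx%s but this model was built for %dx%d (time x channels)",
        i, nrow(tr), ncol(tr), Tn, Cn))
    }
  }

  pcache <- new.env(parent = emptyenv())
  P <- function(nm) {
    if (is.null(pcache[[nm]])) {
      if (is.null(model$params[[nm]])) stop("missing parameter ", nm)
      pcache[[nm]] <- agParam(tp, model$params[[nm]], nm)
    }
    pcache[[nm]]
  }
  bnStats <- list()
  bn <- function(x, name) {
    rs <- model$running[[name]]
    id <- agBatchNorm(tp, x, P(paste0(name, ".gamma")), P(paste0(name, ".beta")),
                      training = training,
                      runMean = rs$mean, runVar = rs$var)
    if (training)
      bnStats[[name]] <<- list(mean = attr(id, "batchMean"),
                               var = attr(id, "batchVar"))
    as.integer(id)
  }
  linear <- function(x, wname) {
    agBcastAdd(tp, agMatmul(tp, x, P(paste0(wname, ".W"))),
               P(paste0(wname, ".b")))
  }
  mlp <- function(x, name) {
    h <- agGelu(tp, agBcastAdd(tp, agMatmul(tp, x, P(paste0(name, ".W1"))),
                               P(paste0(name, ".b1"))))
    agBcastAdd(tp, agMatmul(tp, h, P(paste0(name, ".W2"))), P(paste0(name, ".b2")))
  }
  # multi-head attention per trial: query/kv given as (B*Lq) x d and
  # (B*Lk) x d batch-major nodes; returns list(concat = per-trial L x
  # (nH*dV) ids merged back to (B*Lq) x wide, out = after MLP + residual)
  msaBlock <- function(qNode, kvNode, lq, lk, name, biasName = NULL) {
    outs <- vector("list", B)
    for (b in seq_len(B)) {
      qb <- agRows(tp, qNode, ((b - 1L) * lq + 1L):(b * lq))
      kb <- agRows(tp, kvNode, ((b - 1L) * lk + 1L):(b * lk))
      heads <- vector("list", a@nHeads)
      for (h in seq_len(a@nHeads)) {
        Q <- agMatmul(tp, qb, P(sprintf("%s.msa.Wq%d", name, h)))
        K <- agMatmul(tp, kb, P(sprintf("%s.msa.Wk%d", name, h)))
        V <- agMatmul(tp, kb, P(sprintf("%s.msa.Wv%d", name, h)))
        sc <- agScale(tp, agMatmul(tp, Q, agTranspose(tp, K)), 1 / sqrt(a@dK))
        if (!is.null(biasName)) {
          L <- lq
          idx <- (relativeBiasIndex(lq, lk, L) - 1L) * a@nHeads + h
          sc <- agAdd(tp, sc, agGather(tp, P(biasName), idx))
        }
        heads[[h]] <- agMatmul(tp, agSoftmaxRows(tp, sc), V)
      }
      outs[[b]] <- agCbind(tp, heads)
    }
    wide <- agRbind(tp, outs)                       # (B*lq) x (nH*dV)
    y <- mlp(wide, paste0(name, ".mlp"))            # (B*lq) x d
    if (cfg@useResidual) y <- agAdd(tp, qNode, y)
    list(wide = wide, out = y)
  }
  addPosInput <- function(x, name, len) {
    if (a@positionKind == "absolute") {
      agAdd(tp, x, agRows(tp, P(paste0(name, ".pos")), rep(seq_len(len), B)))
    } else if (a@positionKind == "sincos") {
      pe <- sincosEmbedding(len, d)
      agAdd(tp, x, agConst(tp, pe[rep(seq_len(len), B), , drop = FALSE]))
    } else x
  }
  relBias <- function(name) {
    if (a@positionKind == "relative" &&
        !is.null(model$params[[paste0(name, ".bias")]]))
      paste0(name, ".bias") else NULL
  }

  stages <- list()

  # --- embeddings of the raw trial on both axes
  embT <- NULL
  if (!is.null(model$params[["embT.W"]])) {
    Xt <- agConst(tp, do.call(rbind, batch))        # (B*T) x C, batch-major
    embT <- linear(Xt, "embT")                      # (B*T) x d
    stages$embT <- dim(tapeValue(tp, embT))
  }
  embC <- NULL
  if (!is.null(model$params[["embC.W"]])) {
    Xc <- agConst(tp, do.call(rbind, lapply(batch, t)))   # (B*C) x T
    embC <- linear(Xc, "embC")                      # (B*C) x d
    stages$embC <- dim(tapeValue(tp, embC))
  }

  # --- TF stream
  tfOut <- NULL
  if (tfOn) {
    x <- bn(embT, "tf.bn1")
    if (cfg@useTfLstm) {
      x <- lstmForward(tp, x, P, B, Tn, cfg@lstmHidden, d)
      x <- bn(x, "tf.bn2")
      stages$tfLstm <- dim(tapeValue(tp, x))
    }
    if (cfg@useTfTransformer) {
      x <- addPosInput(x, "tf", Tn)
      blk <- msaBlock(x, x, Tn, Tn, "tf", relBias("tf"))
      stages$tfMsa <- dim(tapeValue(tp, blk$wide))
      x <- blk$out
    }
    tfOut <- x                                      # (B*T) x d
    stages$tf <- dim(tapeValue(tp, tfOut))
  }

  # --- SF stream
  sfOut <- NULL
  if (cfg@useSf) {
    x <- bn(embC, "sf.bn")
    x <- addPosInput(x, "sf", Cn)
    blk <- msaBlock(x, x, Cn, Cn, "sf", relBias("sf"))
    stages$sfMsa <- dim(tapeValue(tp, blk$wide))
    sfOut <- blk$out                                # (B*C) x d
    stages$sf <- dim(tapeValue(tp, sfOut))
  }

  # --- TSCross blocks
  ctOut <- NULL
  if (cfg@useSingleT) {
    blk <- msaBlock(embC, tfOut, Cn, Tn, "ct", relBias("ct"))
    stages$singleTMsa <- dim(tapeValue(tp, blk$wide))
    ctOut <- blk$out                                # (B*C) x d
    stages$singleT <- dim(tapeValue(tp, ctOut))
  }
  ccOut <- NULL
  if (cfg@useSingleC) {
    kv <- if (cfg@useSf) sfOut else embC            # fallback: raw channel embedding
    blk <- msaBlock(embT, kv, Tn, Cn, "cc", relBias("cc"))
    stages$singleCMsa <- dim(tapeValue(tp, blk$wide))
    ccOut <- blk$out                                # (B*T) x d
    stages$singleC <- dim(tapeValue(tp, ccOut))
  }

  # --- classifier: concatenate streams along the sequence axis, pool, MLP
  streamNames <- classifierStreams(tfOn, cfg@useSf, cfg@useSingleT,
                                   cfg@useSingleC)
  if (!length(streamNames)) stop("no stream feeds the classifier")
  srcs <- list(tf = list(node = tfOut, len = Tn),
               sf = list(node = sfOut, len = Cn),
               singleT = list(node = ctOut, len = Cn),
               singleC = list(node = ccOut, len = Tn))
  pooled <- vector("list", B)
  for (b in seq_len(B)) {
    parts <- lapply(streamNames, function(s) {
      src <- srcs[[s]]
      agRows(tp, src$node, ((b - 1L) * src$len + 1L):(b * src$len))
    })
    pooled[[b]] <- agColMeans(tp, agRbind(tp, parts))     # 1 x d
  }
  stages$pooled <- dim(tapeValue(tp, pooled[[1L]]))
  pb <- agRbind(tp, pooled)                               # B x d
  h1 <- agGelu(tp, agBcastAdd(tp, agMatmul(tp, pb, P("clf.W1")), P("clf.b1")))
  logits <- agBcastAdd(tp, agMatmul(tp, h1, P("clf.W2")), P("clf.b2"))
  stages$logits <- dim(tapeValue(tp, logits))

  list(tape = tp, logits = logits, stages = stages, bnStats = bnStats,
       streams = streamNames,
       streamNodes = list(tf = tfOut, sf = sfOut, singleT = ctOut,
                          singleC = ccOut))
}

# Batched single-layer LSTM over the time axis; x is (B*T) x d batch-major,
# returns (B*T) x H batch-major. Standard gate order (input, forget, cell,
# output); initial state zero.
lstmForward <- function(tp, x, P, B, Tn, H, d) {
  Wx <- P("tf.lstm.Wx"); Wh <- P("tf.lstm.Wh"); bb <- P("tf.lstm.b")
  h <- agConst(tp, matrix(0, B, H))
  cc <- agConst(tp, matrix(0, B, H))
  hs <- vector("list", Tn)
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  for (t in seq_len(Tn)) {
    xt <- agRows(tp, x, (seq_len(B) - 1L) * Tn + t)
    z <- agBcastAdd(tp, agAdd(tp, agMatmul(tp, xt, Wx), agMatmul(tp, h, Wh)), bb)
    ig <- agSigmoid(tp, agCols(tp, z, i1))
    fg <- agSigmoid(tp, agCols(tp, z, i2))
    gg <- agTanh(tp, agCols(tp, z, i3))
    og <- agSigmoid(tp, agCols(tp, z, i4))
    cc <- agAdd(tp, agMul(tp, fg, cc), agMul(tp, ig, gg))
    h <- agMul(tp, og, agTanh(tp, cc))
    hs[[t]] <- h
  }
  tm <- agRbind(tp, hs)                     # time-major: row (t-1)*B + b
  perm <- as.vector(vapply(seq_len(B), function(b) (seq_len(Tn) - 1L) * B + b,
                           integer(Tn)))
  agRows(tp, tm, perm)                      # back to batch-major
}

#' Run the model on trials
#'
#' Evaluation-mode forward pass: batch-norm layers use their running
#' moments, so the output is a deterministic function of the weights and
#' the input.
#'
#' @param model a model from [initModel()] or [trainModel()].
#' @param trials a single T x C matrix or a list of them.
#' @return matrix of class probabilities, one row per trial, rows summing
#'   to 1.
#' @export
modelForward <- function(model, trials) {
  if (is.matrix(trials)) trials <- list(trials)
  fc <- forwardCore(model, trials, training = FALSE)
  softmaxRows(tapeValue(fc$tape, fc$logits))
}

#' Predict class labels
#'
#' @param model a trained model.
#' @param trials a trial matrix or list of trial matrices.
#' @return integer vector of 0-based predicted labels.
#' @export
predictLabels <- function(model, trials) {
  p <- modelForward(model, trials)
  max.col(p, ties.method = "first") - 1L
}

#' Inspect intermediate shapes of a forward pass
#'
#' Runs a single trial through the model and returns the dimensions of each
#' stage's representation (embeddings, per-stream attention concatenations
#' and outputs, pooled vector, logits), for contract checks against the
#' published layer table.
#'
#' @param model a model object.
#' @param trial a T x C matrix; defaults to a zero trial of the model's
#'   geometry.
#' @return named list of integer dimension vectors.
#' @export
modelStageShapes <- function(model, trial = NULL) {
  if (is.null(trial)) trial <- matrix(0, model$tSteps, model$nChannels)
  forwardCore(model, list(trial), training = FALSE)$stages
}

# ---------------------------------------------------------------------------
# Spec-level stage operations (single-trial convenience wrappers)

#' Embed the time axis of a trial
#'
#' Linear channel-to-embedding map followed by batch normalization — the
#' entry stage of the temporal-feature stream.
#'
#' @param model a model object (must include the TF stream or SingleC).
#' @param trial a T x C matrix.
#' @param training use batch statistics (TRUE) or running moments (FALSE).
#' @return T x dModel matrix.
#' @export
embedTimeAxis <- function(model, trial, training = FALSE) {
  stopifnot(is.matrix(trial))
  if (ncol(trial) != model$nChannels)
    stop(sprintf("trial has %d channels but the embedding was built for %d",
                 ncol(trial), model$nChannels))
  tp <- tapeNew()
  x <- agBcastAdd(tp, agMatmul(tp, agConst(tp, trial),
                               agParam(tp, model$params[["embT.W"]], "embT.W")),
                  agParam(tp, model$params[["embT.b"]], "embT.b"))
  rs <- model$running[["tf.bn1"]]
  if (!is.null(rs)) {
    x <- agBatchNorm(tp, x,
                     agParam(tp, model$params[["tf.bn1.gamma"]], "g"),
                     agParam(tp, model$params[["tf.bn1.beta"]], "b"),
                     training = training, runMean = rs$mean, runVar = rs$var)
  }
  tapeValue(tp, x)
}

#' Temporal-feature stream output for one trial
#'
#' @param model a model object with the TF stream enabled.
#' @param trial a T x C matrix.
#' @return T x dModel matrix.
#' @export
tfForward <- function(model, trial) {
  fc <- forwardCore(model, list(trial), training = FALSE)
  node <- fc$streamNodes$tf
  if (is.null(node)) stop("the TF stream is disabled in this model")
  tapeValue(fc$tape, node)
}

#' Spatial-feature stream output for one trial
#'
#' @param model a model object with the SF stream enabled.
#' @param trial a T x C matrix.
#' @return C x dModel matrix.
#' @export
sfForward <- function(model, trial) {
  fc <- forwardCore(model, list(trial), training = FALSE)
  node <- fc$streamNodes$sf
  if (is.null(node)) stop("the SF stream is disabled in this model")
  tapeValue(fc$tape, node)
}

#' Temporal-spatial cross block outputs for one trial
#'
#' `tscrossSingleT` returns the channel-axis output (channel sequence
#' querying the temporal representation); `tscrossSingleC` the time-axis
#' output (time sequence querying the spatial representation).
#'
#' @param model a model object with the corresponding block enabled.
#' @param trial a T x C matrix.
#' @return C x dModel (`tscrossSingleT`) or T x dModel (`tscrossSingleC`)
#'   matrix.
#' @export
tscrossSingleT <- function(model, trial) {
  fc <- forwardCore(model, list(trial), training = FALSE)
  node <- fc$streamNodes$singleT
  if (is.null(node)) stop("TSCross-SingleT is disabled in this model")
  tapeValue(fc$tape, node)
}

#' @rdname tscrossSingleT
#' @export
tscrossSingleC <- function(model, trial) {
  fc <- forwardCore(model, list(trial), training = FALSE)
  node <- fc$streamNodes$singleC
  if (is.null(node)) stop("TSCross-SingleC is disabled in this model")
  tapeValue(fc$tape, node)
}

#' Classify a set of stream representations
#'
#' Concatenates the given stream matrices along the sequence axis, applies
#' global average pooling, the two fully connected layers, and softmax.
#'
#' @param model a model object (supplies the classifier weights).
#' @param streams nonempty list of L x dModel matrices.
#' @return probability vector of length `nClasses`, summing to 1.
#' @export
classifierForward <- function(model, streams) {
  if (!length(streams)) stop("empty stream list: nothing to classify")
  d <- model$cfg@attention@dModel
  for (s in streams) {
    if (!is.matrix(s) || ncol(s) != d)
      stop(sprintf("stream width %s does not match dModel %d", ncol(s), d))
  }
  pooled <- matrix(colMeans(do.call(rbind, streams)), 1L)
  h1 <- geluMat(pooled %*% model$params[["clf.W1"]] +
                  matrix(model$params[["clf.b1"]], 1L))
  logits <- h1 %*% model$params[["clf.W2"]] + matrix(model$params[["clf.b2"]], 1L)
  as.vector(softmaxRows(logits))
}

# ---------------------------------------------------------------------------
# Checkpointing

#' Save a model checkpoint
#'
#' Writes weights, running moments, geometry, and the full [ModelConfig-class]
#' as one self-describing file; [loadCheckpoint()] restores it losslessly.
#'
#' @param model a model object.
#' @param path output file path.
#' @param overwrite replace an existing file.
#' @export
saveCheckpoint <- function(model, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("refusing to clobber existing file ", path,
         " (use overwrite = TRUE)")
  saveRDS(list(format = "tscanet-checkpoint", version = 1L, model = model),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [saveCheckpoint()].
#' @return the model object.
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("unreadable checkpoint ", path, ": ", conditionMessage(e)))
  if (!identical(obj$format, "tscanet-checkpoint"))
    stop(path, " is not a model checkpoint")
  obj$model
}
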