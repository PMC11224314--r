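# Loss, Adam optimization, stratified fold construction, and the
# cross-validation orchestration.

#' Mean cross-entropy of predicted probabilities
#'
#' `L = -(1/N) sum_n log p_n(y_n)` with one-hot targets; logs are clamped
#' at 1e-12 so a confident wrong prediction yields a large finite loss.
#'
#' @param predicted matrix of probability rows (trials x classes).
#' @param labels 0-based integer labels.
#' @return nonnegative scalar.
#' @examples
#' crossEntropyLoss(matrix(1 / 26, 2, 26), c(0, 25))  # log(26)
#' @export
crossEntropyLoss <- function(predicted, labels) {
  predicted <- as.matrix(predicted)
  if (nrow(predicted) != length(labels))
    stop("number of probability rows and labels differ")
  if (any(labels < 0L | labels >= ncol(predicted)))
    stop("labels out of range")
  rs <- rowSums(predicted)
  if (any(abs(rs - 1) > 1e-6) || any(predicted < -1e-12))
    stop("predicted rows must be probability distributions (sum to 1)")
  p <- predicted[cbind(seq_len(nrow(predicted)), labels + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

#' Stratified k-fold split
#'
#' Partitions trial indices into k folds, stratified by class: within each
#' class the (index-sorted) members are dealt round-robin after a seeded
#' shuffle, so every test fold holds ~1/k of each class and the split
#' depends only on the multiset of labels and the seed. Classes with fewer
#' than k members trigger a warning and an unstratified seeded split.
#'
#' @param labels integer class labels (0-based), one per trial.
#' @param k number of folds (default 5, the 4:1 protocol).
#' @param seed integer seed.
#' @return list with `assignments` (0-based fold id per trial), `train` and
#'   `test` (lists of 1-based index vectors per fold), `k`, and `seed`.
#' @export
makeFolds <- function(labels, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  n <- length(labels)
  if (n < k) stop("fewer trials than folds")
  assignments <- integer(n)
  counts <- table(labels)
  if (any(counts < k)) {
    warning("some classes have fewer than ", k,
            " members; falling back to an unstratified split")
    withSeed(seed, {
      assignments <- (sample(n) %% k)
    })
  } else {
    withSeed(seed, {
      for (cl in sort(unique(labels))) {
        idx <- sort(which(labels == cl))
        idx <- idx[sample(length(idx))]
        assignments[idx] <- (seq_along(idx) - 1L) %% k
      }
    })
  }
  train <- lapply(0:(k - 1L), function(f) which(assignments != f))
  test <- lapply(0:(k - 1L), function(f) which(assignments == f))
  list(assignments = as.integer(assignments), train = train, test = test,
       k = k, seed = as.integer(seed))
}

# One Adam step over the named parameter list; state carries first/second
# moments and the step counter. Weight decay is added to the raw gradient
# (classical Adam-with-L2, the convention of the published protocol).
adamStep <- function(params, grads, state, lr, weightDecay,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]] + weightDecay * params[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  params
}

#' Train a model
#'
#' Minimizes the cross-entropy with Adam under the configured protocol.
#' All randomness (weight initialization, epoch shuffling) derives from
#' `trainCfg@seed`, so identical seeds give identical final weights.
#' Batch-norm running moments are updated with momentum 0.1 for
#' evaluation-mode forward passes.
#'
#' @param dataset a [LabeledDataset-class].
#' @param modelCfg a [ModelConfig-class].
#' @param trainCfg a [TrainConfig-class].
#' @param indices optional 1-based subset of trials to train on.
#' @param shuffle reshuffle the trial order every epoch (TRUE); FALSE keeps
#'   a fixed batch order.
#' @param verbose print per-epoch loss.
#' @return list with `model` (trained), `history` (data.frame epoch /
#'   loss / accuracy, training-batch statistics), and `trainCfg`.
#' @export
trainModel <- function(dataset, modelCfg, trainCfg, indices = NULL,
                       shuffle = TRUE, verbose = FALSE) {
  validObject(trainCfg)
  if (!nTrials(dataset)) stop("empty dataset")
  if (is.null(indices)) indices <- seq_len(nTrials(dataset))
  d <- trialDim(dataset)
  model <- initModel(modelCfg, d[1L], d[2L],
                     seed = deriveSeed(trainCfg@seed, "init"))
  labels <- dataset@labels[indices]
  trialsList <- dataset@trials[indices]
  n <- length(indices)
  state <- new.env(parent = emptyenv())
  state$t <- 0L; state$m <- list(); state$v <- list()
  momentum <- 0.1
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))

  for (epoch in seq_len(trainCfg@epochs)) {
    ord <- if (shuffle)
      withSeed(deriveSeed(trainCfg@seed, paste0("epoch", epoch)), sample(n))
    else seq_len(n)
    starts <- seq(1L, n, by = trainCfg@batchSize)
    totalLoss <- 0
    correct <- 0L
    for (bi in seq_along(starts)) {
      sel <- ord[starts[bi]:min(starts[bi] + trainCfg@batchSize - 1L, n)]
      fc <- forwardCore(model, trialsList[sel], training = TRUE)
      lossNode <- agCrossEntropyLogits(fc$tape, fc$logits,
                                       labels[sel] + 1L)
      loss <- as.numeric(tapeValue(fc$tape, lossNode))
      if (!is.finite(loss)) {
        stop(sprintf("non-finite loss at epoch %d, batch %d", epoch, bi))
      }
      logits <- tapeValue(fc$tape, fc$logits)
      correct <- correct + sum(max.col(logits, ties.method = "first") - 1L ==
                                 labels[sel])
      totalLoss <- totalLoss + loss * length(sel)
      grads <- tapeBackward(fc$tape, lossNode)
      model$params <- adamStep(model$params, grads, state,
                               trainCfg@learningRate, trainCfg@weightDecay)
      for (nm in names(fc$bnStats)) {
        rs <- model$running[[nm]]
        model$running[[nm]] <- list(
          mean = (1 - momentum) * rs$mean + momentum * fc$bnStats[[nm]]$mean,
          var = (1 - momentum) * rs$var + momentum * fc$bnStats[[nm]]$var)
      }
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss = totalLoss / n, accuracy = correct / n))
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f  acc %.3f", epoch,
                      trainCfg@epochs, totalLoss / n, correct / n))
  }
  list(model = model, history = history, trainCfg = trainCfg)
}

#' k-fold cross-validation of the full training protocol
#'
#' Builds a stratified fold split, trains one independent model per fold on
#' its training portion, evaluates on the held-out fold, and aggregates the
#' per-fold metrics into the cross-fold mean and sample standard deviation.
#'
#' @param dataset a [LabeledDataset-class].
#' @param modelCfg a [ModelConfig-class].
#' @param trainCfg a [TrainConfig-class]; fold f trains with a seed derived
#'   from `trainCfg@seed` and f.
#' @param k number of folds (default 5).
#' @param verbose print per-fold progress.
#' @return a [FoldResult-class].
#' @export
runCrossValidation <- function(dataset, modelCfg, trainCfg, k = 5L,
                               verbose = FALSE) {
  folds <- makeFolds(dataset@labels, k = k, seed = trainCfg@seed)
  reports <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    foldCfg <- trainCfg
    foldCfg@seed <- deriveSeed(trainCfg@seed, paste0("fold", f))
    fit <- trainModel(dataset, modelCfg, foldCfg, indices = folds$train[[f]])
    reports[[f]] <- evaluateModel(fit$model, dataset, folds$test[[f]])
    if (verbose)
      message(sprintf("fold %d/%d  accuracy %.2f%%", f, folds$k,
                      reports[[f]]@accuracy))
  }
  foldTab <- do.call(rbind, lapply(seq_along(reports), function(f) {
    mm <- macroMetrics(reports[[f]])
    data.frame(fold = f, accuracy = mm[["accuracy"]],
               precision = mm[["precision"]], recall = mm[["recall"]],
               f1 = mm[["f1"]])
  }))
  agg <- aggregateFolds(reports)
  new("FoldResult", reports = reports, foldMetrics = foldTab,
      mean = stats::setNames(agg$mean, agg$metric),
      sd = stats::setNames(agg$sd, agg$metric),
      seed = trainCfg@seed)
}
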