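# Loss closed forms, stratified folds, the training loop's determinism and
# learning behaviour, and the ablation harness enumeration.

test_that("cross-entropy reproduces its closed forms", {
  onehot <- diag(3)[c(1, 3, 2), ]
  expect_equal(crossEntropyLoss(onehot, c(0L, 2L, 1L)), 0, tolerance = 1e-10)
  expect_equal(crossEntropyLoss(matrix(1 / 26, 4, 26), c(0L, 5L, 12L, 25L)),
               log(26), tolerance = 1e-12)
  # 3 trials, 2 classes, pencil-and-paper sum
  p <- matrix(c(0.9, 0.1, 0.2, 0.8, 0.5, 0.5), 3, 2, byrow = TRUE)
  want <- -(log(0.9) + log(0.8) + log(0.5)) / 3
  expect_equal(crossEntropyLoss(p, c(0L, 1L, 0L)), want, tolerance = 1e-12)
  expect_error(crossEntropyLoss(matrix(c(0.3, 0.3), 1, 2), 0L),
               "probability")
  expect_error(crossEntropyLoss(matrix(c(0.5, 0.5), 1, 2), 2L),
               "out of range")
})

test_that("stratified folds partition each class evenly and reproducibly", {
  labels <- rep(0:25, each = 10)
  f1 <- makeFolds(labels, k = 5, seed = 42)
  expect_equal(sort(unique(f1$assignments)), 0:4)
  for (fold in seq_len(5)) {
    testLabels <- labels[f1$test[[fold]]]
    expect_equal(unname(table(testLabels)), rep(2L, 26), ignore_attr = TRUE)
    expect_length(intersect(f1$train[[fold]], f1$test[[fold]]), 0)
    expect_setequal(c(f1$train[[fold]], f1$test[[fold]]), seq_along(labels))
  }
  f2 <- makeFolds(labels, k = 5, seed = 42)
  expect_identical(f1$assignments, f2$assignments)
  expect_false(identical(f1$assignments,
                         makeFolds(labels, k = 5, seed = 43)$assignments))
})

test_that("fold membership depends only on class and within-class rank", {
  labels <- rep(0:2, each = 10)
  ord <- tscanet:::withSeed(1, sample(length(labels)))
  shuffled <- labels[ord]
  f1 <- makeFolds(labels, k = 5, seed = 7)
  f2 <- makeFolds(shuffled, k = 5, seed = 7)
  # identify each trial by (class, rank of its index among its class)
  rankIn <- function(labs) {
    stats::ave(seq_along(labs), labs, FUN = function(ix) rank(ix))
  }
  key1 <- paste(labels, rankIn(labels), f1$assignments)
  key2 <- paste(shuffled, rankIn(shuffled), f2$assignments)
  expect_setequal(key1, key2)
})

test_that("classes smaller than k trigger the unstratified fallback", {
  labels <- c(rep(0L, 8), rep(1L, 3))
  expect_warning(f <- makeFolds(labels, k = 5, seed = 1), "unstratified")
  expect_equal(sort(unique(f$assignments)), 0:4)
  expect_error(makeFolds(labels, k = 1, seed = 1), "at least 2")
})

test_that("training reduces the loss on separable data and is seed-deterministic", {
  ds <- tinyDataset()
  mc <- modelConfig(nClasses = 3L,
                    attention = attentionConfig(nHeads = 1L, dModel = 8L,
                                                dQ = 4L, dK = 4L, dV = 4L),
                    lstmHidden = 8L, mlpOut = 8L)
  tc <- trainConfig(learningRate = 1e-3, epochs = 8L, batchSize = 10L,
                    seed = 5L)
  fit1 <- trainModel(ds, mc, tc)
  expect_equal(nrow(fit1$history), 8L)
  expect_lt(tail(fit1$history$loss, 1), fit1$history$loss[1])
  fit2 <- trainModel(ds, mc, tc)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_identical(fit1$history$loss, fit2$history$loss)
})

test_that("zero learning rate freezes the loss under a fixed batch order", {
  ds <- tinyDataset()
  mc <- modelConfig(nClasses = 3L,
                    attention = attentionConfig(nHeads = 1L, dModel = 8L,
                                                dQ = 4L, dK = 4L, dV = 4L),
                    lstmHidden = 8L, mlpOut = 8L)
  tc <- new("TrainConfig", learningRate = 1e-30, weightDecay = 0,
            epochs = 3L, batchSize = 10L, seed = 5L)
  fit <- trainModel(ds, mc, tc, shuffle = FALSE)
  expect_equal(fit$history$loss[2], fit$history$loss[1], tolerance = 1e-8)
  expect_equal(fit$history$loss[3], fit$history$loss[1], tolerance = 1e-8)
})

test_that("cross-validation aggregates per-fold reports consistently", {
  ds <- tinyDataset()
  mc <- modelConfig(nClasses = 3L,
                    attention = attentionConfig(nHeads = 1L, dModel = 8L,
                                                dQ = 4L, dK = 4L, dV = 4L,
                                                positionKind = "none"),
                    lstmHidden = 8L, mlpOut = 8L)
  tc <- trainConfig(learningRate = 1e-3, epochs = 3L, batchSize = 10L,
                    seed = 9L)
  fr <- runCrossValidation(ds, mc, tc, k = 5L)
  expect_length(fr@reports, 5L)
  expect_equal(nrow(foldMetrics(fr)), 5L)
  accs <- foldMetrics(fr)$accuracy
  expect_equal(fr@mean[["accuracy"]], mean(accs), tolerance = 1e-9)
  expect_equal(fr@sd[["accuracy"]], sd(accs), tolerance = 1e-9)
  expect_identical(fr@seed, 9L)
})

test_that("ablation grids enumerate the published variant counts", {
  expect_length(ablationGrid("components"), 7L)
  expect_length(ablationGrid("position"), 4L)
  expect_length(ablationGrid("heads-dims"), 6L)
  expect_error(ablationGrid("foo"), "components, position, heads-dims")
  labs <- vapply(ablationGrid("heads-dims"), `[[`, "", "label")
  expect_setequal(labs, c("heads8-dims64", "heads8-dims128", "heads8-dims256",
                          "heads16-dims64", "heads16-dims128",
                          "heads16-dims256"))
})

test_that("the ablation suite trains every variant and reports invalid configs", {
  ds <- tinyDataset()
  mc <- modelConfig(nClasses = 3L,
                    attention = attentionConfig(nHeads = 1L, dModel = 8L,
                                                dQ = 4L, dK = 4L, dV = 4L),
                    lstmHidden = 8L, mlpOut = 8L)
  tc <- trainConfig(learningRate = 1e-3, epochs = 1L, batchSize = 10L,
                    seed = 3L)
  grid <- list(
    list(label = "full", overrides = list()),
    list(label = "no-SF", overrides = list(useSf = FALSE)),
    list(label = "nothing", overrides = list(
      useTfLstm = FALSE, useTfTransformer = FALSE, useSf = FALSE,
      useSingleT = FALSE, useSingleC = FALSE)))
  tab <- runAblationSuite(ds, grid, mc, tc)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$status, c("ok", "ok", "invalid"))
  expect_match(tab$message[3], "classifier")
  expect_true(all(is.finite(tab$accuracy[1:2])))
  expect_true(is.na(tab$accuracy[3]))
  expect_lt(tab$parameters[2], tab$parameters[1])
  # empty grid: empty table, no error
  empty <- runAblationSuite(ds, list(), mc, tc)
  expect_true(is.null(empty) || nrow(empty) == 0L)
})
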