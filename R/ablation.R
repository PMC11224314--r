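# Ablation harness: the three published grids (model components, position
# embedding, attention heads x per-head dims) plus custom variant lists,
# each variant trained and evaluated identically.

#' The named ablation grids
#'
#' `"components"` enumerates the seven published component-toggle rows
#' (dropping in turn the TF LSTM, the TF Transformer, SF, both cross
#' blocks, SingleC only, SingleT only, and the full model);
#' `"position"` the four position-embedding kinds; `"heads-dims"` the six
#' combinations of 8/16 heads with per-head width 64/128/256.
#'
#' @param name one of `"components"`, `"position"`, `"heads-dims"`.
#' @return list of variants; each variant is a list with `label` and
#'   `overrides` (named config overrides).
#' @export
ablationGrid <- function(name) {
  grids <- list(
    components = list(
      list(label = "no-TF-LSTM", overrides = list(useTfLstm = FALSE)),
      list(label = "no-TF-Transformer", overrides = list(useTfTransformer = FALSE)),
      list(label = "no-SF", overrides = list(useSf = FALSE)),
      list(label = "no-TSCross", overrides = list(useSingleT = FALSE,
                                                  useSingleC = FALSE)),
      list(label = "no-SingleC", overrides = list(useSingleC = FALSE)),
      list(label = "no-SingleT", overrides = list(useSingleT = FALSE)),
      list(label = "full", overrides = list())
    ),
    position = lapply(positionKinds[c(2L, 3L, 4L, 1L)], function(kind)
      list(label = paste0("position-", kind),
           overrides = list(positionKind = kind))),
    `heads-dims` = {
      combos <- expand.grid(heads = c(8L, 16L), dims = c(64L, 128L, 256L))
      lapply(seq_len(nrow(combos)), function(i)
        list(label = sprintf("heads%d-dims%d", combos$heads[i], combos$dims[i]),
             overrides = list(nHeads = combos$heads[i],
                              dQ = combos$dims[i], dK = combos$dims[i],
                              dV = combos$dims[i])))
    })
  if (!name %in% names(grids))
    stop("unknown grid ", deparse(name), "; valid grids: ",
         paste(names(grids), collapse = ", "))
  grids[[name]]
}

# apply variant overrides to a base ModelConfig; attention-level fields are
# routed into the nested AttentionConfig
applyOverrides <- function(baseCfg, overrides) {
  a <- baseCfg@attention
  attnFields <- c("nHeads", "dModel", "dQ", "dK", "dV", "positionKind",
                  "crossPositionBias")
  for (nm in names(overrides)) {
    if (nm %in% attnFields) slot(a, nm) <- overrides[[nm]]
    else slot(baseCfg, nm) <- overrides[[nm]]
  }
  baseCfg@attention <- a
  validObject(a)
  validObject(baseCfg)
  baseCfg
}

configFingerprint <- function(cfg) {
  a <- cfg@attention
  paste0("N", cfg@nClasses, "-d", a@dModel, "-h", a@nHeads, "-q", a@dQ,
         "-v", a@dV, "-pos", a@positionKind,
         "-L", as.integer(cfg@useTfLstm), "T", as.integer(cfg@useTfTransformer),
         "S", as.integer(cfg@useSf), "sT", as.integer(cfg@useSingleT),
         "sC", as.integer(cfg@useSingleC), "R", as.integer(cfg@useResidual))
}

#' Run an ablation suite
#'
#' Trains and evaluates one model per variant of a grid under an identical
#' protocol and data split. A variant whose toggles leave the classifier
#' without input is recorded as invalid (with the validity message), never
#' silently skipped.
#'
#' @param dataset a [LabeledDataset-class].
#' @param grid a grid name accepted by [ablationGrid()] or a list of
#'   variants in the same shape.
#' @param baseModelCfg the [ModelConfig-class] the overrides are applied to.
#' @param trainCfg a [TrainConfig-class]; every variant trains from
#'   `trainCfg@seed`.
#' @param evaluation `"holdout"` (train on 4/5 of a stratified split,
#'   evaluate on the rest) or `"cv"` (full k-fold, slower).
#' @param k folds for the split.
#' @return data.frame with one row per variant: `variant`, `fingerprint`,
#'   `status` ("ok"/"invalid"), `message`, `parameters`, `accuracy`,
#'   `precision`, `recall`, `f1` (percent; NA for invalid rows), `sdAccuracy`
#'   (cv only), `seed`.
#' @export
runAblationSuite <- function(dataset, grid, baseModelCfg, trainCfg,
                             evaluation = c("holdout", "cv"), k = 5L) {
  evaluation <- match.arg(evaluation)
  variants <- if (is.character(grid)) ablationGrid(grid) else grid
  rows <- vector("list", length(variants))
  for (i in seq_along(variants)) {
    v <- variants[[i]]
    row <- data.frame(variant = v$label, fingerprint = NA_character_,
                      status = "ok", message = "", parameters = NA_integer_,
                      accuracy = NA_real_, precision = NA_real_,
                      recall = NA_real_, f1 = NA_real_,
                      sdAccuracy = NA_real_, seed = trainCfg@seed)
    cfg <- tryCatch(applyOverrides(baseModelCfg, v$overrides),
                    error = function(e) e)
    if (inherits(cfg, "error")) {
      row$status <- "invalid"
      row$message <- conditionMessage(cfg)
      rows[[i]] <- row
      next
    }
    row$fingerprint <- configFingerprint(cfg)
    d <- trialDim(dataset)
    row$parameters <- countParameters(
      initModel(cfg, d[1L], d[2L], seed = deriveSeed(trainCfg@seed, "init")))
    if (evaluation == "holdout") {
      folds <- makeFolds(dataset@labels, k = k, seed = trainCfg@seed)
      fit <- trainModel(dataset, cfg, trainCfg, indices = folds$train[[1L]])
      rep1 <- evaluateModel(fit$model, dataset, folds$test[[1L]])
      mm <- macroMetrics(rep1)
      row$accuracy <- mm[["accuracy"]]; row$precision <- mm[["precision"]]
      row$recall <- mm[["recall"]]; row$f1 <- mm[["f1"]]
    } else {
      fr <- runCrossValidation(dataset, cfg, trainCfg, k = k)
      row$accuracy <- fr@mean[["accuracy"]]
      row$precision <- fr@mean[["precision"]]
      row$recall <- fr@mean[["recall"]]
      row$f1 <- fr@mean[["f1"]]
      row$sdAccuracy <- fr@sd[["accuracy"]]
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}
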