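#' @import methods
NULL

# Central S4 containers. Trials are time-major T x C real matrices of
# spike-band activity; labels are 0-based integer classes in [0, nClasses).

#' Labelled collection of neural trials
#'
#' Holds a set of single-trial activity matrices (rows = time steps,
#' columns = recording channels) together with 0-based integer class labels
#' and a provenance record (the generating spec for synthetic data, or the
#' source file path for loaded data).
#'
#' @slot trials list of T x C numeric matrices, all with identical dimensions.
#' @slot labels integer vector, one label per trial, values in `[0, nClasses)`.
#' @slot nClasses total number of classes the labels are drawn from.
#' @slot provenance list describing how the dataset was produced.
#'
#' @seealso [generateDataset()], [loadTrialDataset()]
#' @export
setClass("LabeledDataset",
  representation(trials = "list", labels = "integer", nClasses = "integer",
                 provenance = "list"),
  prototype(trials = list(), labels = integer(0), nClasses = 1L,
            provenance = list())
)

setValidity("LabeledDataset", function(object) {
  msgs <- character(0)
  if (length(object@trials) != length(object@labels))
    msgs <- c(msgs, "number of trials and labels differ")
  if (length(object@nClasses) != 1L || object@nClasses < 1L)
    msgs <- c(msgs, "nClasses must be a single positive integer")
  if (length(object@labels) &&
      (any(object@labels < 0L) || any(object@labels >= object@nClasses)))
    msgs <- c(msgs, "labels must lie in [0, nClasses)")
  if (length(object@trials)) {
    d1 <- dim(object@trials[[1L]])
    for (i in seq_along(object@trials)) {
      tr <- object@trials[[i]]
      if (!is.matrix(tr) || !is.numeric(tr)) {
        msgs <- c(msgs, sprintf("trial %d is not a numeric matrix", i))
        break
      }
      if (!identical(dim(tr), d1)) {
        msgs <- c(msgs, sprintf("trial %d has dimensions %dx%d, expected %dx%d",
                                i, nrow(tr), ncol(tr), d1[1L], d1[2L]))
        break
      }
      if (!all(is.finite(tr))) {
        msgs <- c(msgs, sprintf("trial %d contains non-finite values", i))
        break
      }
    }
    if (d1[1L] < 2L || d1[2L] < 2L)
      msgs <- c(msgs, "trials need at least 2 time steps and 2 channels")
  }
  if (length(msgs)) msgs else TRUE
})

#' Confusion-matrix evaluation report
#'
#' Confusion matrix (rows = true labels, columns = predictions) plus
#' per-class and macro-averaged precision/recall/F1 and overall accuracy,
#' all expressed in percent.
#'
#' @slot confusion N x N integer matrix of counts.
#' @slot perClass data.frame with one row per class: precision, recall, f1
#'   (percent), support, and a `defined` flag that is FALSE where a
#'   zero-denominator sentinel was substituted.
#' @slot accuracy overall accuracy in percent.
#' @slot macroPrecision,macroRecall,macroF1 unweighted macro averages in
#'   percent.
#' @slot flags list of bookkeeping flags (e.g. `undefined` for an empty
#'   matrix, `excluded` classes with no true and no predicted instances).
#'
#' @seealso [overallMetrics()]
#' @export
setClass("MetricsReport",
  representation(confusion = "matrix", perClass = "data.frame",
                 accuracy = "numeric", macroPrecision = "numeric",
                 macroRecall = "numeric", macroF1 = "numeric",
                 flags = "list")
)

setValidity("MetricsReport", function(object) {
  msgs <- character(0)
  cm <- object@confusion
  if (nrow(cm) != ncol(cm)) msgs <- c(msgs, "confusion matrix must be square")
  if (length(cm) && any(cm < 0)) msgs <- c(msgs, "confusion counts must be nonnegative")
  pc <- object@perClass
  if (nrow(pc) && nrow(pc) != nrow(cm))
    msgs <- c(msgs, "perClass rows must match confusion dimension")
  ok <- function(x) !length(x) || is.na(x) || (x >= 0 && x <= 100)
  if (!ok(object@accuracy)) msgs <- c(msgs, "accuracy must be in [0, 100]")
  if (length(msgs)) msgs else TRUE
})

#' Cross-validation result
#'
#' Per-fold metric reports together with the cross-fold arithmetic mean and
#' sample standard deviation (denominator k - 1) of each metric.
#'
#' @slot reports list of [MetricsReport-class], one per fold.
#' @slot foldMetrics data.frame with one row per fold (accuracy and macro
#'   precision/recall/F1, percent).
#' @slot mean,sd named numeric vectors across folds.
#' @slot seed the integer seed the fold split and training runs derived from.
#'
#' @seealso [runCrossValidation()], [aggregateFolds()]
#' @export
setClass("FoldResult",
  representation(reports = "list", foldMetrics = "data.frame",
                 mean = "numeric", sd = "numeric", seed = "integer")
)

# Configuration classes -------------------------------------------------------

#' Multi-head attention configuration
#'
#' @slot nHeads number of attention heads.
#' @slot dModel embedding width of the sequences entering attention.
#' @slot dQ,dK,dV per-head query/key/value projection widths (dQ must equal
#'   dK for dot-product compatibility).
#' @slot positionKind one of "relative", "absolute", "sincos", "none".
#' @slot crossPositionBias whether the relative bias is also applied inside
#'   the cross-attention blocks (default FALSE: query and key there index
#'   different axes, so a relative offset has no meaning).
#' @export
setClass("AttentionConfig",
  representation(nHeads = "integer", dModel = "integer", dQ = "integer",
                 dK = "integer", dV = "integer", positionKind = "character",
                 crossPositionBias = "logical")
)

positionKinds <- c("relative", "absolute", "sincos", "none")

setValidity("AttentionConfig", function(object) {
  msgs <- character(0)
  for (s in c("nHeads", "dModel", "dQ", "dK", "dV")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 1L)
      msgs <- c(msgs, sprintf("%s must be a single positive integer", s))
  }
  if (object@dQ != object@dK)
    msgs <- c(msgs, "dQ must equal dK (dot-product compatibility)")
  if (!object@positionKind %in% positionKinds)
    msgs <- c(msgs, paste0("positionKind must be one of: ",
                           paste(positionKinds, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Full model configuration
#'
#' Architecture hyperparameters and the ablation toggles for the five
#' streams: the temporal-feature LSTM and Transformer stages, the
#' spatial-feature stream, and the two temporal-spatial cross blocks.
#'
#' @slot nClasses number of output classes.
#' @slot attention an [AttentionConfig-class].
#' @slot lstmHidden LSTM hidden width (equals the embedding width).
#' @slot useTfLstm,useTfTransformer,useSf,useSingleT,useSingleC component
#'   toggles; all TRUE for the full model.
#' @slot useResidual include a residual connection from each encoder block's
#'   input to its MLP output (FALSE gives the strict layer-table reading).
#' @slot mlpOut output width of each block's MLP (must equal `dModel`).
#' @export
setClass("ModelConfig",
  representation(nClasses = "integer", attention = "AttentionConfig",
                 lstmHidden = "integer", useTfLstm = "logical",
                 useTfTransformer = "logical", useSf = "logical",
                 useSingleT = "logical", useSingleC = "logical",
                 useResidual = "logical", mlpOut = "integer")
)

setValidity("ModelConfig", function(object) {
  msgs <- character(0)
  if (object@nClasses < 2L) msgs <- c(msgs, "nClasses must be at least 2")
  if (object@mlpOut != object@attention@dModel)
    msgs <- c(msgs, "mlpOut must equal attention dModel")
  if (object@lstmHidden != object@attention@dModel)
    msgs <- c(msgs, "lstmHidden must equal attention dModel (stream widths)")
  tfOn <- object@useTfLstm || object@useTfTransformer
  streams <- classifierStreams(tfOn, object@useSf,
                               object@useSingleT, object@useSingleC)
  if (length(streams) == 0L)
    msgs <- c(msgs, "no stream feeds the classifier under these toggles")
  if (object@useSingleT && !tfOn)
    msgs <- c(msgs, "TSCross-SingleT requires the TF stream (its key/value source)")
  if (length(msgs)) msgs else TRUE
})

#' Training configuration
#'
#' @slot learningRate Adam step size.
#' @slot weightDecay L2 coupling added to gradients (decoupled from the
#'   adaptive moments, matching the classical Adam weight-decay convention).
#' @slot epochs number of passes over the training set.
#' @slot batchSize trials per gradient step; a short final batch is kept.
#' @slot seed integer seed recorded in every results artifact.
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", weightDecay = "numeric",
                 epochs = "integer", batchSize = "integer", seed = "integer")
)

setValidity("TrainConfig", function(object) {
  msgs <- character(0)
  if (object@learningRate <= 0) msgs <- c(msgs, "learningRate must be positive")
  if (object@weightDecay < 0) msgs <- c(msgs, "weightDecay must be nonnegative")
  if (object@epochs < 1L) msgs <- c(msgs, "epochs must be positive")
  if (object@batchSize < 1L) msgs <- c(msgs, "batchSize must be positive")
  if (is.na(object@seed)) msgs <- c(msgs, "seed is mandatory")
  if (length(msgs)) msgs else TRUE
})

#' Synthetic trial-generator specification
#'
#' Parameters of the class-templated microelectrode-array-like trial
#' generator; see [generateDataset()].
#'
#' @slot tSteps,nChannels,nClasses,trialsPerClass dataset geometry.
#' @slot bumpsPerClass number of localized activity bumps per class template.
#' @slot bumpAmplitude peak template amplitude (arbitrary activity units).
#' @slot bumpTimeWidth Gaussian time s.d. of a bump, in time steps.
#' @slot bumpChannelSpan Gaussian channel s.d. of a bump, in channels.
#' @slot timeJitterSd per-trial global temporal jitter s.d., in time steps.
#' @slot noiseSd additive Gaussian noise s.d.
#' @slot nonneg rectify trials at zero to mimic spike-band power.
#' @slot seed mandatory integer seed; generation is a pure function of the
#'   spec including the seed.
#' @export
setClass("SyntheticSpec",
  representation(tSteps = "integer", nChannels = "integer",
                 nClasses = "integer", trialsPerClass = "integer",
                 bumpsPerClass = "integer", bumpAmplitude = "numeric",
                 bumpTimeWidth = "numeric", bumpChannelSpan = "numeric",
                 timeJitterSd = "numeric", noiseSd = "numeric",
                 nonneg = "logical", seed = "integer")
)

setValidity("SyntheticSpec", function(object) {
  msgs <- character(0)
  for (s in c("tSteps", "nChannels", "nClasses", "trialsPerClass",
              "bumpsPerClass")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 1L)
      msgs <- c(msgs, sprintf("%s must be a single positive integer", s))
  }
  if (!length(msgs)) {
    if (object@tSteps < 2L) msgs <- c(msgs, "tSteps must be at least 2")
    if (object@nChannels < 2L) msgs <- c(msgs, "nChannels must be at least 2")
    if (object@bumpAmplitude < 0) msgs <- c(msgs, "bumpAmplitude must be nonnegative")
    if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be nonnegative")
    if (object@timeJitterSd < 0) msgs <- c(msgs, "timeJitterSd must be nonnegative")
    if (object@bumpTimeWidth <= 0) msgs <- c(msgs, "bumpTimeWidth must be positive")
    if (object@bumpChannelSpan <= 0) msgs <- c(msgs, "bumpChannelSpan must be positive")
    if (is.na(object@seed)) msgs <- c(msgs, "seed is mandatory")
    # a bump must fit inside the trial with a 2-sigma margin on each side
    if (4 * object@bumpTimeWidth >= object@tSteps)
      msgs <- c(msgs, sprintf(
        "bumpTimeWidth %g too large: a bump needs 4 x width < tSteps = %d",
        object@bumpTimeWidth, object@tSteps))
    if (4 * object@bumpChannelSpan >= object@nChannels)
      msgs <- c(msgs, sprintf(
        "bumpChannelSpan %g too large: a bump needs 4 x span < nChannels = %d",
        object@bumpChannelSpan, object@nChannels))
  }
  if (length(msgs)) msgs else TRUE
})
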