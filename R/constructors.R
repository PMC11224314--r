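# User-facing constructors with the published defaults, plus accessors and
# show methods.

#' Create an attention configuration
#'
#' Defaults follow the published architecture: 16 heads, per-head
#' query/key/value width 128 (concatenated width 16 x 128 = 2048), model
#' width 256, and relative position embedding.
#'
#' @param nHeads number of attention heads.
#' @param dModel embedding width.
#' @param dQ,dK,dV per-head projection widths; `dQ` must equal `dK`.
#' @param positionKind one of `"relative"`, `"absolute"`, `"sincos"`,
#'   `"none"`.
#' @param crossPositionBias apply the relative bias inside cross-attention
#'   blocks too (default FALSE; the offset between a channel index and a
#'   time index has no natural meaning).
#' @return an [AttentionConfig-class] object.
#' @examples
#' cfg <- attentionConfig(nHeads = 2, dModel = 32, dQ = 16, dK = 16, dV = 16)
#' @export
attentionConfig <- function(nHeads = 16L, dModel = 256L, dQ = 128L,
                            dK = 128L, dV = 128L, positionKind = "relative",
                            crossPositionBias = FALSE) {
  positionKind <- match.arg(positionKind, positionKinds)
  new("AttentionConfig", nHeads = as.integer(nHeads),
      dModel = as.integer(dModel), dQ = as.integer(dQ), dK = as.integer(dK),
      dV = as.integer(dV), positionKind = positionKind,
      crossPositionBias = isTRUE(crossPositionBias))
}

#' Create a model configuration
#'
#' @param nClasses number of character classes (default 26 lowercase
#'   letters).
#' @param attention an [AttentionConfig-class]; defaults to
#'   [attentionConfig()].
#' @param lstmHidden LSTM hidden width (default 256, equal to the embedding
#'   width).
#' @param useTfLstm,useTfTransformer,useSf,useSingleT,useSingleC ablation
#'   toggles for the five streams; all TRUE for the full model.
#' @param useResidual residual connection from each encoder block input to
#'   its MLP output.
#' @param mlpOut block MLP output width; must equal the attention `dModel`.
#' @return a [ModelConfig-class] object.
#' @examples
#' cfg <- modelConfig(nClasses = 3,
#'                    attention = attentionConfig(nHeads = 2, dModel = 32,
#'                                                dQ = 16, dK = 16, dV = 16),
#'                    lstmHidden = 32, mlpOut = 32)
#' @export
modelConfig <- function(nClasses = 26L, attention = attentionConfig(),
                        lstmHidden = attention@dModel, useTfLstm = TRUE,
                        useTfTransformer = TRUE, useSf = TRUE,
                        useSingleT = TRUE, useSingleC = TRUE,
                        useResidual = TRUE, mlpOut = attention@dModel) {
  new("ModelConfig", nClasses = as.integer(nClasses), attention = attention,
      lstmHidden = as.integer(lstmHidden), useTfLstm = isTRUE(useTfLstm),
      useTfTransformer = isTRUE(useTfTransformer), useSf = isTRUE(useSf),
      useSingleT = isTRUE(useSingleT), useSingleC = isTRUE(useSingleC),
      useResidual = isTRUE(useResidual), mlpOut = as.integer(mlpOut))
}

#' Create a training configuration
#'
#' Defaults reproduce the published protocol: Adam with learning rate 3e-5,
#' weight decay 1e-4, 400 epochs, batch size 8.
#'
#' @param learningRate Adam step size.
#' @param weightDecay L2 penalty coupled into the gradients.
#' @param epochs training epochs.
#' @param batchSize trials per gradient step.
#' @param seed integer seed; mandatory, recorded in every artifact.
#' @return a [TrainConfig-class] object.
#' @export
trainConfig <- function(learningRate = 3e-5, weightDecay = 1e-4,
                        epochs = 400L, batchSize = 8L, seed = 1L) {
  new("TrainConfig", learningRate = as.numeric(learningRate),
      weightDecay = as.numeric(weightDecay), epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), seed = as.integer(seed))
}

#' Create a synthetic-data specification
#'
#' Defaults emulate the imagined-handwriting recordings the model was
#' designed for: 201 time steps x 192 channels, 26 classes with balanced
#' trial counts (122 per class, about 3,172 total), four smooth activity
#' bumps per class template, mild temporal jitter and additive noise, and
#' rectification at zero.
#'
#' @param tSteps,nChannels trial geometry (time steps x channels).
#' @param nClasses number of classes.
#' @param trialsPerClass trials generated per class.
#' @param bumpsPerClass localized activity bumps per class template.
#' @param bumpAmplitude peak bump amplitude.
#' @param bumpTimeWidth Gaussian s.d. of a bump along time, in time steps.
#' @param bumpChannelSpan Gaussian s.d. of a bump across channels.
#' @param timeJitterSd s.d. of the per-trial global temporal jitter.
#' @param noiseSd additive Gaussian noise s.d.
#' @param nonneg rectify trials at zero.
#' @param seed mandatory integer seed.
#' @return a [SyntheticSpec-class] object.
#' @examples
#' spec <- syntheticSpec(tSteps = 20, nChannels = 8, nClasses = 3,
#'                       trialsPerClass = 10, seed = 7,
#'                       bumpTimeWidth = 2, bumpChannelSpan = 1)
#' @export
syntheticSpec <- function(tSteps = 201L, nChannels = 192L, nClasses = 26L,
                          trialsPerClass = 122L, bumpsPerClass = 4L,
                          bumpAmplitude = 1, bumpTimeWidth = 8,
                          bumpChannelSpan = 12, timeJitterSd = 2,
                          noiseSd = 0.25, nonneg = TRUE, seed = 1L) {
  new("SyntheticSpec", tSteps = as.integer(tSteps),
      nChannels = as.integer(nChannels), nClasses = as.integer(nClasses),
      trialsPerClass = as.integer(trialsPerClass),
      bumpsPerClass = as.integer(bumpsPerClass),
      bumpAmplitude = as.numeric(bumpAmplitude),
      bumpTimeWidth = as.numeric(bumpTimeWidth),
      bumpChannelSpan = as.numeric(bumpChannelSpan),
      timeJitterSd = as.numeric(timeJitterSd), noiseSd = as.numeric(noiseSd),
      nonneg = isTRUE(nonneg), seed = as.integer(seed))
}

#' Assemble a labelled dataset from trials and labels
#'
#' @param trials list of T x C numeric matrices.
#' @param labels integer labels in `[0, nClasses)`.
#' @param nClasses number of classes; defaults to `max(labels) + 1`.
#' @param provenance free-form provenance record.
#' @return a [LabeledDataset-class].
#' @export
labeledDataset <- function(trials, labels, nClasses = max(labels) + 1L,
                           provenance = list()) {
  new("LabeledDataset", trials = trials, labels = as.integer(labels),
      nClasses = as.integer(nClasses), provenance = provenance)
}

# Accessors -------------------------------------------------------------------

#' @describeIn LabeledDataset-class list of trial matrices.
#' @param object a `LabeledDataset`.
#' @export
setGeneric("trials", function(object) standardGeneric("trials"))

#' @export
setMethod("trials", "LabeledDataset", function(object) object@trials)

#' @describeIn LabeledDataset-class integer labels (0-based).
#' @export
setGeneric("trialLabels", function(object) standardGeneric("trialLabels"))

#' @export
setMethod("trialLabels", "LabeledDataset", function(object) object@labels)

#' Number of classes
#' @param object a dataset, model config, or metrics report.
#' @export
setGeneric("nClasses", function(object) standardGeneric("nClasses"))

#' @export
setMethod("nClasses", "LabeledDataset", function(object) object@nClasses)

#' @export
setMethod("nClasses", "ModelConfig", function(object) object@nClasses)

#' Number of trials in a dataset
#' @param object a `LabeledDataset`.
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))

#' @export
setMethod("nTrials", "LabeledDataset", function(object) length(object@trials))

#' Trial geometry (time steps, channels)
#' @param object a `LabeledDataset`.
#' @return integer vector `c(tSteps, nChannels)`.
#' @export
setGeneric("trialDim", function(object) standardGeneric("trialDim"))

#' @export
setMethod("trialDim", "LabeledDataset", function(object) {
  if (!length(object@trials)) return(c(NA_integer_, NA_integer_))
  dim(object@trials[[1L]])
})

#' Confusion matrix of a metrics report
#' @param object a `MetricsReport`.
#' @export
setGeneric("confusion", function(object) standardGeneric("confusion"))

#' @export
setMethod("confusion", "MetricsReport", function(object) object@confusion)

#' Per-class precision/recall/F1 table (percent)
#' @param object a `MetricsReport`.
#' @export
setGeneric("perClass", function(object) standardGeneric("perClass"))

#' @export
setMethod("perClass", "MetricsReport", function(object) object@perClass)

#' Macro-level metric summary
#' @param object a `MetricsReport` or `FoldResult`.
#' @return named numeric vector (percent).
#' @export
setGeneric("macroMetrics", function(object) standardGeneric("macroMetrics"))

#' @export
setMethod("macroMetrics", "MetricsReport", function(object) {
  c(accuracy = object@accuracy, precision = object@macroPrecision,
    recall = object@macroRecall, f1 = object@macroF1)
})

#' @export
setMethod("macroMetrics", "FoldResult", function(object) object@mean)

#' Per-fold metric table of a cross-validation result
#' @param object a `FoldResult`.
#' @export
setGeneric("foldMetrics", function(object) standardGeneric("foldMetrics"))

#' @export
setMethod("foldMetrics", "FoldResult", function(object) object@foldMetrics)

# show methods ----------------------------------------------------------------

setMethod("show", "LabeledDataset", function(object) {
  d <- trialDim(object)
  cat(sprintf(
    "LabeledDataset: %d trials (%s x %s time x channels), %d classes\n",
    nTrials(object), d[1L], d[2L], nClasses(object)))
  if (length(object@labels)) {
    tab <- table(object@labels)
    cat(sprintf("  trials per class: %s\n",
                if (length(unique(tab)) == 1L) as.character(tab[[1L]])
                else paste0(min(tab), "-", max(tab))))
  }
  src <- object@provenance$source
  if (!is.null(src)) cat("  provenance:", src, "\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(paste0(
    "MetricsReport: %d classes, %d trials\n",
    "  accuracy %.2f%% | macro precision %.2f%% | recall %.2f%% | F1 %.2f%%\n"),
    nrow(object@confusion), sum(object@confusion), object@accuracy,
    object@macroPrecision, object@macroRecall, object@macroF1))
  if (isTRUE(object@flags$undefined))
    cat("  (empty evaluation: metrics undefined)\n")
})

setMethod("show", "FoldResult", function(object) {
  k <- length(object@reports)
  cat(sprintf("FoldResult: %d folds (seed %d)\n", k, object@seed))
  for (m in names(object@mean)) {
    cat(sprintf("  %-9s %.2f +/- %.2f\n", m, object@mean[[m]],
                object@sd[[m]]))
  }
})

setMethod("show", "ModelConfig", function(object) {
  a <- object@attention
  on <- function(x) if (x) "on" else "off"
  cat(sprintf(paste0(
    "ModelConfig: %d classes, dModel %d, %d heads (dq=dk=%d, dv=%d), ",
    "position %s\n  TF-LSTM %s | TF-Transformer %s | SF %s | SingleT %s | ",
    "SingleC %s | residual %s\n"),
    object@nClasses, a@dModel, a@nHeads, a@dK, a@dV, a@positionKind,
    on(object@useTfLstm), on(object@useTfTransformer), on(object@useSf),
    on(object@useSingleT), on(object@useSingleC), on(object@useResidual)))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0(
    "SyntheticSpec: %d classes x %d trials, %d x %d (time x channels)\n",
    "  %d bumps/class, amplitude %g, widths (t %g, c %g), jitter %g, ",
    "noise %g, seed %d\n"),
    object@nClasses, object@trialsPerClass, object@tSteps, object@nChannels,
    object@bumpsPerClass, object@bumpAmplitude, object@bumpTimeWidth,
    object@bumpChannelSpan, object@timeJitterSd, object@noiseSd, object@seed))
})

# Which representations reach the classifier under a toggle set: the two
# cross outputs when present, otherwise the enabled TF/SF outputs directly.
classifierStreams <- function(tfOn, sfOn, singleT, singleC) {
  if (singleT || singleC) {
    c(if (singleT) "singleT", if (singleC) "singleC")
  } else {
    c(if (tfOn) "tf", if (sfOn) "sf")
  }
}
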