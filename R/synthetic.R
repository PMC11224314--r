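# Synthetic microelectrode-array-like trial generator: class-specific
# spatiotemporal templates built from smooth Gaussian activity bumps, plus
# per-trial temporal jitter and additive noise, rectified to mimic
# nonnegative spike-band power. Generation is a pure function of the spec
# (including its seed).

# evaluate a class template at given bump parameters with a global time
# shift; bumps are separable Gaussian profiles in time and channel
templateFromBumps <- function(bumps, tSteps, nChannels, shift = 0) {
  out <- matrix(0, tSteps, nChannels)
  tAxis <- seq_len(tSteps)
  cAxis <- seq_len(nChannels)
  for (b in bumps) {
    prof <- exp(-((tAxis - (b$t0 + shift))^2) / (2 * b$tw^2))
    span <- exp(-((cAxis - b$c0)^2) / (2 * b$cw^2))
    out <- out + b$amp * outer(prof, span)
  }
  out
}

#' Generate a synthetic labelled trial dataset
#'
#' For every class a fixed template of localized time-window x channel-band
#' activity bumps is drawn once from the seeded generator; each trial is
#' the template re-evaluated under a per-trial global temporal jitter, plus
#' i.i.d. Gaussian noise, rectified at zero when `nonneg`. The dataset is
#' bitwise reproducible from the spec.
#'
#' @param spec a [SyntheticSpec-class].
#' @return a [LabeledDataset-class]; the provenance records the spec and
#'   the per-class bump parameters and noiseless templates.
#' @examples
#' spec <- syntheticSpec(tSteps = 20, nChannels = 8, nClasses = 2,
#'                       trialsPerClass = 3, bumpTimeWidth = 2,
#'                       bumpChannelSpan = 1, seed = 11)
#' ds <- generateDataset(spec)
#' nTrials(ds)
#' @export
generateDataset <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  Tn <- spec@tSteps; Cn <- spec@nChannels
  tw <- spec@bumpTimeWidth; cw <- spec@bumpChannelSpan
  withSeed(spec@seed, {
    classBumps <- lapply(seq_len(spec@nClasses), function(cl) {
      lapply(seq_len(spec@bumpsPerClass), function(b) {
        list(t0 = stats::runif(1, 1 + 2 * tw, Tn - 2 * tw),
             c0 = stats::runif(1, 1 + 2 * cw, Cn - 2 * cw),
             tw = tw, cw = cw,
             amp = spec@bumpAmplitude * stats::runif(1, 0.7, 1))
      })
    })
    trialsList <- vector("list", spec@nClasses * spec@trialsPerClass)
    labels <- integer(length(trialsList))
    i <- 0L
    for (cl in seq_len(spec@nClasses)) {
      for (r in seq_len(spec@trialsPerClass)) {
        i <- i + 1L
        shift <- if (spec@timeJitterSd > 0)
          stats::rnorm(1, sd = spec@timeJitterSd) else 0
        tr <- templateFromBumps(classBumps[[cl]], Tn, Cn, shift)
        if (spec@noiseSd > 0)
          tr <- tr + matrix(stats::rnorm(Tn * Cn, sd = spec@noiseSd), Tn, Cn)
        if (spec@nonneg) tr <- pmax(tr, 0)
        trialsList[[i]] <- tr
        labels[i] <- cl - 1L
      }
    }
    templates <- lapply(classBumps, templateFromBumps,
                        tSteps = Tn, nChannels = Cn)
    labeledDataset(trialsList, labels, spec@nClasses,
                   provenance = list(source = "synthetic", spec = spec,
                                     bumps = classBumps,
                                     templates = templates))
  })
}

#' Class templates of a synthetic dataset
#'
#' @param dataset a dataset produced by [generateDataset()].
#' @return list of noiseless T x C class template matrices.
#' @export
classTemplates <- function(dataset) {
  tpl <- dataset@provenance$templates
  if (is.null(tpl)) stop("dataset carries no generator templates")
  tpl
}

#' Nearest-template baseline accuracy
#'
#' Classifies every trial by the nearest class template in Euclidean
#' distance — a brute-force baseline independent of the network, used to
#' confirm that a generated dataset is separable.
#'
#' @param dataset a [LabeledDataset-class].
#' @param templates list of T x C templates, one per class; defaults to the
#'   generator templates in the dataset provenance.
#' @return accuracy in percent.
#' @export
nearestTemplateAccuracy <- function(dataset, templates = classTemplates(dataset)) {
  stopifnot(length(templates) == nClasses(dataset))
  correct <- 0L
  for (i in seq_len(nTrials(dataset))) {
    dists <- vapply(templates, function(tpl)
      sum((dataset@trials[[i]] - tpl)^2), 0)
    if (which.min(dists) - 1L == dataset@labels[i]) correct <- correct + 1L
  }
  100 * correct / nTrials(dataset)
}

#' Within- and between-class distance summary
#'
#' Reports the mean pairwise Euclidean trial distance within each class and
#' between each class pair, plus the between/within ratio per pair (a ratio
#' near 1 means the classes are not separable at the trial level).
#'
#' @param dataset a [LabeledDataset-class].
#' @param maxPerClass cap on trials per class entering the pairwise sums
#'   (the first `maxPerClass` per class, for determinism).
#' @return list with `within` (data.frame class / meanDist / n) and
#'   `between` (data.frame classA / classB / meanDist / ratio; empty for a
#'   single-class dataset).
#' @export
separabilityReport <- function(dataset, maxPerClass = 30L) {
  byClass <- split(seq_len(nTrials(dataset)), dataset@labels)
  byClass <- lapply(byClass, utils::head, n = maxPerClass)
  flat <- lapply(byClass, function(idx)
    t(vapply(dataset@trials[idx], as.vector,
             numeric(length(dataset@trials[[1L]])))))
  classes <- as.integer(names(byClass))
  within <- data.frame(class = classes,
                       meanDist = vapply(flat, function(m) {
                         if (nrow(m) < 2L) return(0)
                         mean(stats::dist(m))
                       }, 0),
                       n = vapply(flat, nrow, 1L))
  pairs <- if (length(classes) > 1L) utils::combn(seq_along(classes), 2L) else
    matrix(integer(0), 2L, 0L)
  between <- data.frame(classA = integer(0), classB = integer(0),
                        meanDist = numeric(0), ratio = numeric(0))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1L, p]; b <- pairs[2L, p]
    cross <- sqrt(outer(rowSums(flat[[a]]^2), rowSums(flat[[b]]^2), "+") -
                    2 * tcrossprod(flat[[a]], flat[[b]]))
    wa <- within$meanDist[a]; wb <- within$meanDist[b]
    md <- mean(cross)
    between <- rbind(between, data.frame(
      classA = classes[a], classB = classes[b], meanDist = md,
      ratio = if (wa + wb > 0) md / ((wa + wb) / 2) else Inf))
  }
  list(within = within, between = between)
}

# ---------------------------------------------------------------------------
# Dataset container I/O

#' Save a labelled dataset
#'
#' Writes a self-describing single-file container (R serialization) with
#' members `trials` (n x T x C array), `labels` (integer vector), and
#' `meta` (provenance, label mapping, geometry).
#'
#' @param dataset a [LabeledDataset-class].
#' @param path output path (conventionally `.rds`).
#' @param overwrite replace an existing file.
#' @export
saveDataset <- function(dataset, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("refusing to clobber existing file ", path,
         " (use overwrite = TRUE)")
  d <- trialDim(dataset)
  arr <- array(0, c(nTrials(dataset), d[1L], d[2L]))
  for (i in seq_len(nTrials(dataset))) arr[i, , ] <- dataset@trials[[i]]
  meta <- dataset@provenance
  meta$nClasses <- nClasses(dataset)
  saveRDS(list(format = "tscanet-dataset", version = 1L, trials = arr,
               labels = dataset@labels, meta = meta), path)
  invisible(path)
}

#' Load a trial dataset from a container file
#'
#' Accepts the container written by [saveDataset()]: an R serialization
#' holding `trials` (n x T x C array), `labels`, and `meta`. Shapes are
#' validated against the declared geometry; labels with gaps (e.g. classes
#' {0, 2}) are remapped to a dense `[0, N)` range with the mapping recorded
#' in the provenance.
#'
#' @param path input file.
#' @param tSteps,nChannels optional expected geometry; a mismatch is
#'   rejected stating found vs. expected.
#' @return a [LabeledDataset-class].
#' @export
loadTrialDataset <- function(path, tSteps = NULL, nChannels = NULL) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read ", path, " (truncated or not an R serialization): ",
         conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "tscanet-dataset"))
    stop(path, " is not a recognized trial container; supported: ",
         "tscanet-dataset R serialization (see saveDataset)")
  arr <- obj$trials
  if (!is.array(arr) || length(dim(arr)) != 3L)
    stop("container member 'trials' must be an n x T x C array")
  n <- dim(arr)[1L]
  if (!is.null(tSteps) && dim(arr)[2L] != tSteps)
    stop(sprintf("time dimension mismatch: found %d, expected %d",
                 dim(arr)[2L], tSteps))
  if (!is.null(nChannels) && dim(arr)[3L] != nChannels)
    stop(sprintf("channel dimension mismatch: found %d, expected %d",
                 dim(arr)[3L], nChannels))
  rawLabels <- as.integer(obj$labels)
  if (length(rawLabels) != n)
    stop(sprintf("label count %d does not match trial count %d",
                 length(rawLabels), n))
  lev <- sort(unique(rawLabels))
  labels <- match(rawLabels, lev) - 1L
  labelMap <- stats::setNames(seq_along(lev) - 1L, lev)
  meta <- if (is.list(obj$meta)) obj$meta else list()
  meta$source <- meta$source %||% path
  meta$labelMap <- labelMap
  trialsList <- lapply(seq_len(n), function(i)
    matrix(arr[i, , ], dim(arr)[2L], dim(arr)[3L]))
  labeledDataset(trialsList, labels, length(lev), provenance = meta)
}
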