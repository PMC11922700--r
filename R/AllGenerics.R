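#' @include AllClasses.R
NULL

#' Accessors for EEG objects
#'
#' `eegData()` returns the channels-by-samples signal matrix, `samplingRate()`
#' the sampling frequency in Hz, `channelNames()` the montage labels,
#' `subjectID()`, `subjectGroup()`, `sessionLag()`, `recordingCondition()` and
#' `blockIndex()` the session metadata. On a [CleanRecording-class],
#' `rejectionMask()` returns the per-sample exclusion mask, `maskIntervals()`
#' the excluded intervals in seconds, and `provenance()` the list of applied
#' preprocessing steps.
#'
#' @param x an [EEGRecording-class] or [CleanRecording-class] object.
#' @return See details per accessor.
#' @name eeg-accessors
NULL

#' @rdname eeg-accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @rdname eeg-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname eeg-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname eeg-accessors
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))
#' @rdname eeg-accessors
#' @export
setGeneric("subjectGroup", function(x) standardGeneric("subjectGroup"))
#' @rdname eeg-accessors
#' @export
setGeneric("sessionLag", function(x) standardGeneric("sessionLag"))
#' @rdname eeg-accessors
#' @export
setGeneric("recordingCondition", function(x) standardGeneric("recordingCondition"))
#' @rdname eeg-accessors
#' @export
setGeneric("blockIndex", function(x) standardGeneric("blockIndex"))
#' @rdname eeg-accessors
#' @export
setGeneric("rejectionMask", function(x) standardGeneric("rejectionMask"))
#' @rdname eeg-accessors
#' @export
setGeneric("maskIntervals", function(x) standardGeneric("maskIntervals"))
#' @rdname eeg-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname eeg-accessors
setMethod("eegData", "EEGRecording", function(x) x@data)
#' @rdname eeg-accessors
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname eeg-accessors
setMethod("channelNames", "EEGRecording", function(x) x@montage$label)
#' @rdname eeg-accessors
setMethod("subjectID", "EEGRecording", function(x) x@subject)
#' @rdname eeg-accessors
setMethod("subjectGroup", "EEGRecording", function(x) x@group)
#' @rdname eeg-accessors
setMethod("sessionLag", "EEGRecording", function(x) x@lag)
#' @rdname eeg-accessors
setMethod("recordingCondition", "EEGRecording", function(x) x@condition)
#' @rdname eeg-accessors
setMethod("blockIndex", "EEGRecording", function(x) x@block)
#' @rdname eeg-accessors
setMethod("rejectionMask", "CleanRecording", function(x) x@mask)
#' @rdname eeg-accessors
setMethod("provenance", "CleanRecording", function(x) x@provenance)

#' @rdname eeg-accessors
setMethod("maskIntervals", "CleanRecording", function(x) {
  maskToIntervals(x@mask, x@fs)
})

# internal: logical mask -> data.frame(start_s, end_s), end exclusive
maskToIntervals <- function(mask, fs) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start_s = (starts[keep] - 1) / fs, end_s = ends[keep] / fs)
}

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("%s: %d ch x %d samples @ %g Hz (%.1f s)\n",
              class(object), nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs))
  cat(sprintf("  subject %s | group %s | lag %s | condition %s | block %d\n",
              object@subject, object@group, object@lag, object@condition,
              object@block))
  if (is(object, "CleanRecording")) {
    cat(sprintf("  %.2f%% samples rejected; steps: %s\n",
                100 * mean(object@mask),
                paste(vapply(object@provenance, `[[`, "", "step"),
                      collapse = " -> ")))
  }
  invisible(object)
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d folds, mean balanced accuracy %.3f (seed %d)\n",
              length(object@foldScores), mean(object@foldScores), object@seed))
  invisible(object)
})

setMethod("show", "SearchResult", function(object) {
  cat(sprintf("SearchResult (%s): %d trials, best mean balanced accuracy %.3f\n",
              object@strategy, nrow(object@trials), object@bestScore))
  invisible(object)
})

setMethod("show", "RandomizationResult", function(object) {
  cat(sprintf(
    "RandomizationResult: %d true vs %d shuffled searches\n  mean true %.3f | mean shuffled %.3f | Welch t(%.1f) = %.2f, p = %.3g\n",
    length(object@trueScores), length(object@shuffledScores),
    mean(object@trueScores), mean(object@shuffledScores),
    object@df, object@statistic, object@pValue))
  invisible(object)
})

setMethod("show", "TransferResult", function(object) {
  cat(sprintf(
    "TransferResult (trained on %s): same-lag sensitivity %.3f, cross-lag %.3f\n",
    object@trainLag, mean(object@sameLag), mean(object@crossLag)))
  invisible(object)
})

#' Extract slots from analysis result objects
#'
#' `trueScores()`/`shuffledScores()` return the per-seed mean balanced
#' accuracies of a [RandomizationResult-class]; `welchStatistic()` and
#' `pValue()` its Welch comparison. `bestScore()`, `bestParams()` and
#' `searchTrials()` read a [SearchResult-class]; `foldScores()` and
#' `cvPredictions()` a [CVResult-class].
#'
#' @param x a result object.
#' @return See details per accessor.
#' @name result-accessors
NULL

#' @rdname result-accessors
#' @export
setGeneric("trueScores", function(x) standardGeneric("trueScores"))
#' @rdname result-accessors
#' @export
setGeneric("shuffledScores", function(x) standardGeneric("shuffledScores"))
#' @rdname result-accessors
#' @export
setGeneric("welchStatistic", function(x) standardGeneric("welchStatistic"))
#' @rdname result-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname result-accessors
#' @export
setGeneric("bestScore", function(x) standardGeneric("bestScore"))
#' @rdname result-accessors
#' @export
setGeneric("bestParams", function(x) standardGeneric("bestParams"))
#' @rdname result-accessors
#' @export
setGeneric("searchTrials", function(x) standardGeneric("searchTrials"))
#' @rdname result-accessors
#' @export
setGeneric("foldScores", function(x) standardGeneric("foldScores"))
#' @rdname result-accessors
#' @export
setGeneric("cvPredictions", function(x) standardGeneric("cvPredictions"))

#' @rdname result-accessors
setMethod("trueScores", "RandomizationResult", function(x) x@trueScores)
#' @rdname result-accessors
setMethod("shuffledScores", "RandomizationResult", function(x) x@shuffledScores)
#' @rdname result-accessors
setMethod("welchStatistic", "RandomizationResult", function(x) x@statistic)
#' @rdname result-accessors
setMethod("pValue", "RandomizationResult", function(x) x@pValue)
#' @rdname result-accessors
setMethod("bestScore", "SearchResult", function(x) x@bestScore)
#' @rdname result-accessors
setMethod("bestParams", "SearchResult", function(x) x@bestParams)
#' @rdname result-accessors
setMethod("searchTrials", "SearchResult", function(x) x@trials)
#' @rdname result-accessors
setMethod("foldScores", "CVResult", function(x) x@foldScores)
#' @rdname result-accessors
setMethod("cvPredictions", "CVResult", function(x) x@predictions)
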