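#' @import methods
#' @importFrom stats predict
NULL

VALID_LAGS <- c("pre", "post1h", "post24h")
VALID_CONDITIONS <- c("eo_sit", "ec_sit", "eo_stand", "ec_stand")
VALID_GROUPS <- c("kicking", "non_kicking")
BLOCK_ORDER <- rep(VALID_CONDITIONS, 2)  # recording order within a session

#' EEGRecording: one block of multichannel EEG
#'
#' A single 2.5-min (by default) resting-EEG block: a channels-by-samples
#' matrix in microvolts plus subject, group, session-lag, condition and block
#' metadata and the electrode montage.
#'
#' @slot data numeric matrix, channels x samples, rownames = channel labels (uV).
#' @slot fs sampling rate in Hz.
#' @slot subject subject identifier.
#' @slot group `"kicking"`, `"non_kicking"` or `NA` (unknown).
#' @slot lag `"pre"`, `"post1h"` or `"post24h"`.
#' @slot condition one of the four crossed eyes-by-posture states
#'   (`"eo_sit"`, `"ec_sit"`, `"eo_stand"`, `"ec_stand"`).
#' @slot block block index 1..8 within the session.
#' @slot montage data.frame with `label`, `x`, `y`, `group` per channel.
#' @export
setClass("EEGRecording",
  representation(
    data = "matrix", fs = "numeric", subject = "character",
    group = "character", lag = "character", condition = "character",
    block = "integer", montage = "data.frame"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (nrow(object@data) != nrow(object@montage)) {
    msg <- c(msg, "channel count must equal montage size")
  }
  if (!is.null(rownames(object@data)) &&
      !identical(rownames(object@data), object@montage$label)) {
    msg <- c(msg, "data rownames must match montage labels")
  }
  if (length(object@fs) != 1 || object@fs <= 0) msg <- c(msg, "fs must be a positive scalar")
  if (!object@lag %in% VALID_LAGS) {
    msg <- c(msg, sprintf("lag must be one of %s", paste(VALID_LAGS, collapse = ", ")))
  }
  if (!object@condition %in% VALID_CONDITIONS) {
    msg <- c(msg, sprintf("condition must be one of %s", paste(VALID_CONDITIONS, collapse = ", ")))
  }
  if (!is.na(object@group) && !object@group %in% VALID_GROUPS) {
    msg <- c(msg, "group must be kicking, non_kicking or NA")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (uV).
#' @param fs sampling rate (Hz).
#' @param subject,group,lag,condition,block metadata; see class slots.
#' @param montage electrode montage; defaults to [montage1010()].
#' @return An [EEGRecording-class] object.
#' @export
EEGRecording <- function(data, fs = 512, subject = "S01", group = NA_character_,
                         lag = "pre", condition = "eo_sit", block = 1L,
                         montage = montage1010()) {
  rownames(data) <- montage$label
  new("EEGRecording", data = data, fs = fs, subject = subject,
      group = as.character(group), lag = lag, condition = condition,
      block = as.integer(block), montage = montage)
}

#' CleanRecording: a preprocessed recording plus its rejection mask
#'
#' Produced by [preprocess()]: the filtered, average-referenced,
#' ocular-cleaned signal together with a per-sample rejection mask (TRUE =
#' excluded) and a provenance list recording every applied step and its
#' parameters.
#'
#' @slot mask logical vector, one entry per sample (TRUE = excluded).
#' @slot provenance list of applied steps with parameters.
#' @export
setClass("CleanRecording",
  contains = "EEGRecording",
  representation(mask = "logical", provenance = "list")
)

setValidity("CleanRecording", function(object) {
  msg <- character()
  if (length(object@mask) != ncol(object@data)) {
    msg <- c(msg, "mask length must equal sample count")
  }
  if (length(object@provenance) == 0) msg <- c(msg, "provenance must be non-empty")
  if (length(msg)) msg else TRUE
})

#' FeatureTable: session-level band-power observations
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' classifier's input: one column per session observation (subject x lag), one
#' row per (condition, channel, band) feature, assay `"bandpower"` in uV^2/Hz.
#' `colData` carries `subject`, `lag`, binary `label`
#' (`"baseline"`/`"post_impact"`) and `group`; `rowData` carries the feature
#' index (`condition`, `channel`, `band`).
#'
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject", "lag", "label", "group")
  if (!all(need %in% colnames(cd))) {
    msg <- c(msg, paste("colData must contain", paste(need, collapse = ", ")))
  } else {
    if (!all(cd$label %in% c("baseline", "post_impact"))) {
      msg <- c(msg, "labels must be baseline/post_impact")
    }
    if (anyDuplicated(paste(cd$subject, cd$lag))) {
      msg <- c(msg, "at most one observation per subject per lag")
    }
  }
  if (!"bandpower" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'bandpower' required")
  }
  if (length(msg)) msg else TRUE
})

#' CVResult: one subject-grouped cross-validation run
#'
#' @slot foldScores per-fold balanced accuracy (length k).
#' @slot foldSubjects list of held-out subject vectors per fold.
#' @slot predictions data.frame of held-out predictions
#'   (columns `subject`, `lag`, `truth`, `pred`, `fold`).
#' @slot selectedFeatures list of selected feature indices per fold.
#' @slot models list of serialised per-fold models (filled only on request).
#' @slot seed the CV seed.
#' @export
setClass("CVResult",
  representation(foldScores = "numeric", foldSubjects = "list",
                 predictions = "data.frame", selectedFeatures = "list",
                 models = "list", seed = "integer")
)

#' SearchResult: one seeded hyperparameter search
#'
#' @slot bestParams list of winning hyperparameters.
#' @slot bestScore best mean cross-validated balanced accuracy.
#' @slot trials data.frame trial log (one row per trial: parameters + score).
#' @slot seed search seed.
#' @slot strategy `"tpe"` or `"random"`.
#' @export
setClass("SearchResult",
  representation(bestParams = "list", bestScore = "numeric",
                 trials = "data.frame", seed = "integer", strategy = "character")
)

#' RandomizationResult: true vs shuffled-label performance
#'
#' @slot trueScores mean balanced accuracy per true-label search seed.
#' @slot shuffledScores same, with labels re-shuffled before each search.
#' @slot statistic Welch t statistic.
#' @slot df Welch-Satterthwaite degrees of freedom.
#' @slot pValue two-tailed p-value.
#' @slot config snapshot of the settings that produced the result.
#' @export
setClass("RandomizationResult",
  representation(trueScores = "numeric", shuffledScores = "numeric",
                 statistic = "numeric", df = "numeric", pValue = "numeric",
                 config = "list")
)

#' TransferResult: cross-lag sensitivity transfer for one training lag
#'
#' @slot trainLag the lag whose post-impact sessions the models were trained on.
#' @slot sameLag per-seed sensitivity at the trained lag (held-out folds).
#' @slot crossLag per-seed sensitivity at the other lag (held-out subjects only).
#' @slot sameLagShuffled,crossLagShuffled shuffled-label baselines.
#' @slot comparisons data.frame of Welch-t comparisons.
#' @export
setClass("TransferResult",
  representation(trainLag = "character", sameLag = "numeric",
                 crossLag = "numeric", sameLagShuffled = "numeric",
                 crossLagShuffled = "numeric", comparisons = "data.frame")
)
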