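#' Canonical EEG frequency bands
#'
#' Half-open intervals `[low, high)` in Hz, so adjacent bands never
#' double-count a frequency bin: delta [1,4), theta [4,8), alpha [8,13),
#' beta1 [13,20), beta2 [20,30), gamma [30,50).
#'
#' @return Named list of `c(low, high)` pairs, in ascending order.
#' @export
bandScheme <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta1 = c(13, 20), beta2 = c(20, 30), gamma = c(30, 50))
}

#' Welch spectral-estimation parameters
#'
#' @param nfft window length in samples (default 512; at 512 Hz this is the
#'   1 s window, giving 1 Hz frequency resolution).
#' @param overlapSec window overlap in seconds (default 0.5).
#' @param taper taper name; `"hann"` (default) or `"hamming"`.
#' @param fs sampling rate the parameters will be used with (for the
#'   window-duration report).
#' @return List of class `"WelchParams"` with an added `windowSec` field
#'   (`nfft / fs`).
#' @export
welchParams <- function(nfft = 512, overlapSec = 0.5, taper = "hann", fs = 512) {
  stopifnot(nfft >= 2, overlapSec >= 0)
  windowSec <- nfft / fs
  if (overlapSec >= windowSec) stop("overlap must be shorter than the window")
  structure(list(nfft = as.integer(nfft), overlapSec = overlapSec,
                 taper = match.arg(taper, c("hann", "hamming")),
                 fs = fs, windowSec = windowSec),
            class = "WelchParams")
}

taperWindow <- function(name, n) {
  k <- seq_len(n) - 1
  switch(name,
         hann = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)),
         hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
         stop("unknown taper"))
}

#' Welch band power with mask-aware window skipping
#'
#' Estimates each channel's power spectral density by averaging one-sided
#' tapered periodograms over sliding windows, skipping every window that
#' touches a masked (rejected) sample, then averages the density over the
#' frequency bins whose centres fall inside each band. Units are uV^2/Hz
#' (density convention; recorded in the result).
#'
#' @param rec an [EEGRecording-class] or [CleanRecording-class] (whose
#'   rejection mask is used automatically), or a channels x samples matrix.
#' @param params a [welchParams()]; its `fs` is overridden by the recording's.
#' @param scheme a [bandScheme()].
#' @param fs sampling rate, required when `rec` is a bare matrix.
#' @param mask optional logical rejection mask (TRUE = excluded).
#' @return List with `power` (channels x bands matrix, uV^2/Hz), `psd`
#'   (channels x frequency bins), `freqs`, `nWindows` (count of contributing
#'   windows), `missing` (TRUE when no fully unmasked window exists) and
#'   `scaling = "density"`.
#' @export
welchBandPower <- function(rec, params = welchParams(), scheme = bandScheme(),
                           fs = NULL, mask = NULL) {
  if (is(rec, "EEGRecording")) {
    dat <- eegData(rec)
    fs <- samplingRate(rec)
    if (is.null(mask) && is(rec, "CleanRecording")) mask <- rejectionMask(rec)
  } else {
    dat <- rec
    if (is.null(fs)) stop("fs required for matrix input")
  }
  nfft <- params$nfft
  n <- ncol(dat)
  nch <- nrow(dat)
  step <- nfft - round(params$overlapSec * fs)
  stopifnot(step >= 1)
  starts <- seq(1L, n - nfft + 1L, by = step)
  if (!is.null(mask) && any(mask)) {
    cm <- cumsum(mask)
    touched <- cm[starts + nfft - 1L] - c(0, cm)[starts] > 0
    starts <- starts[!touched]
  }
  freqs <- (0:(nfft %/% 2)) * fs / nfft
  bandNames <- names(scheme)
  emptyPower <- matrix(NA_real_, nch, length(scheme),
                       dimnames = list(rownames(dat), bandNames))
  if (length(starts) == 0) {
    return(list(power = emptyPower, psd = NULL, freqs = freqs, nWindows = 0L,
                missing = TRUE, scaling = "density"))
  }
  w <- taperWindow(params$taper, nfft)
  norm <- fs * sum(w^2)
  nWin <- length(starts)
  nf <- length(freqs)
  # every (window, channel) segment becomes one column of a single FFT call
  idx <- outer(0:(nfft - 1L), starts, `+`)       # nfft x nWin (sample indices)
  tdat <- t(dat)                                 # samples x channels
  segs <- matrix(tdat[as.vector(idx), , drop = FALSE], nrow = nfft) * w
  X <- stats::mvfft(segs)[seq_len(nf), , drop = FALSE]
  P <- (Mod(X)^2) / norm
  P[2:(nf - 1L), ] <- 2 * P[2:(nf - 1L), ]       # one-sided (DC/Nyquist once)
  P3 <- array(P, c(nf, nWin, nch))               # window fastest, channel last
  psd <- t(vapply(seq_len(nch),
                  function(ch) rowMeans(matrix(P3[, , ch], nrow = nf)),
                  numeric(nf)))
  rownames(psd) <- rownames(dat)
  power <- vapply(scheme, function(b) {
    idx <- which(freqs >= b[1] & freqs < b[2])
    rowMeans(psd[, idx, drop = FALSE])
  }, numeric(nch))
  power <- matrix(power, nch, length(scheme),
                  dimnames = list(rownames(dat), bandNames))
  list(power = power, psd = psd, freqs = freqs, nWindows = length(starts),
       missing = FALSE, scaling = "density")
}

# deterministic feature ordering: condition (recording order) x channel
# (montage order) x band (scheme order)
featureIndex <- function(montage = montage1010(), scheme = bandScheme(),
                         conditions = VALID_CONDITIONS) {
  idx <- expand.grid(band = names(scheme), channel = montage$label,
                     condition = conditions, stringsAsFactors = FALSE)
  idx <- idx[, c("condition", "channel", "band")]
  idx$name <- paste(idx$condition, idx$channel, idx$band, sep = "_")
  idx
}

#' Session-level feature vector from one subject-session's blocks
#'
#' Computes Welch band powers per block and averages them (unweighted) over
#' the blocks of each eyes-by-posture condition, yielding one feature per
#' (condition, channel, band): 4 x 32 x 6 = 768 in the standard design.
#' Conditions with no contributing block (all windows masked) are flagged
#' missing.
#'
#' @param blocks list of [EEGRecording-class]/[CleanRecording-class] objects,
#'   all from one subject and session lag.
#' @param params,scheme Welch settings and band scheme.
#' @return List with `values` (named numeric, one entry per feature, NA where
#'   missing), `missing` (logical per condition), `nBlocks` and `nWindows`
#'   (per condition), `subject`, `lag`, `group`.
#' @export
sessionFeatures <- function(blocks, params = welchParams(), scheme = bandScheme()) {
  stopifnot(length(blocks) >= 1)
  subj <- unique(vapply(blocks, subjectID, ""))
  lag <- unique(vapply(blocks, sessionLag, ""))
  if (length(subj) != 1 || length(lag) != 1) {
    stop("blocks must all come from a single subject and session lag")
  }
  grp <- unique(vapply(blocks, subjectGroup, ""))[1]
  montage <- blocks[[1]]@montage
  idx <- featureIndex(montage, scheme)
  values <- stats::setNames(rep(NA_real_, nrow(idx)), idx$name)
  missing <- stats::setNames(rep(TRUE, length(VALID_CONDITIONS)), VALID_CONDITIONS)
  nBlocks <- nWindows <- stats::setNames(integer(length(VALID_CONDITIONS)),
                                         VALID_CONDITIONS)
  for (cond in VALID_CONDITIONS) {
    condBlocks <- Filter(function(b) recordingCondition(b) == cond, blocks)
    if (!length(condBlocks)) next
    mats <- list()
    for (b in condBlocks) {
      bp <- welchBandPower(b, params, scheme)
      if (!bp$missing) {
        mats[[length(mats) + 1L]] <- bp$power
        nWindows[cond] <- nWindows[cond] + bp$nWindows
      }
    }
    if (!length(mats)) next
    avg <- Reduce(`+`, mats) / length(mats)
    missing[cond] <- FALSE
    nBlocks[cond] <- length(mats)
    sel <- idx$condition == cond
    values[sel] <- avg[cbind(match(idx$channel[sel], montage$label),
                             match(idx$band[sel], names(scheme)))]
  }
  list(values = values, missing = missing, nBlocks = nBlocks,
       nWindows = nWindows, subject = subj, lag = lag, group = grp)
}

#' Assemble the classification feature table for one lag contrast
#'
#' Builds a [FeatureTable-class] (a SummarizedExperiment) from a list of
#' session feature vectors: one column per subject x lag observation with the
#' binary label `baseline` (pre) vs `post_impact` (the requested post lag).
#' Subjects missing either lag are dropped with a warning.
#'
#' @param sessions list of [sessionFeatures()] results.
#' @param lags length-2 character: the baseline lag and the post-impact lag,
#'   default `c("pre", "post24h")`.
#' @return A [FeatureTable-class].
#' @export
assembleFeatureTable <- function(sessions, lags = c("pre", "post24h")) {
  stopifnot(length(lags) == 2, lags[1] == "pre")
  keep <- Filter(function(s) s$lag %in% lags, sessions)
  subj <- vapply(keep, `[[`, "", "subject")
  lag <- vapply(keep, `[[`, "", "lag")
  complete <- names(which(table(unique(data.frame(subj, lag))$subj) == 2))
  dropped <- setdiff(unique(subj), complete)
  if (length(dropped)) {
    warning(length(dropped), " subject(s) missing a lag dropped: ",
            paste(dropped, collapse = ", "))
  }
  sel <- subj %in% complete
  keep <- keep[sel]
  ord <- order(match(vapply(keep, `[[`, "", "subject"), sort(complete)),
               match(vapply(keep, `[[`, "", "lag"), lags))
  keep <- keep[ord]
  if (!length(keep)) stop("no subject has both requested lags")
  mat <- vapply(keep, `[[`, numeric(length(keep[[1]]$values)), "values")
  rn <- names(keep[[1]]$values)
  cd <- S4Vectors::DataFrame(
    subject = vapply(keep, `[[`, "", "subject"),
    lag = vapply(keep, `[[`, "", "lag"),
    label = ifelse(vapply(keep, `[[`, "", "lag") == "pre",
                   "baseline", "post_impact"),
    group = vapply(keep, `[[`, "", "group"))
  rownames(cd) <- paste(cd$subject, cd$lag, sep = ".")
  colnames(mat) <- rownames(cd)
  rd <- featureIndex()
  rd <- rd[match(rn, rd$name), c("condition", "channel", "band")]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(bandpower = mat),
    rowData = S4Vectors::DataFrame(rd), colData = cd)
  rownames(se) <- rn
  methods::new("FeatureTable", se)
}

#' Write / read a feature table as CSV
#'
#' One row per observation; the first columns are `subject`, `lag`, `label`,
#' `group`, followed by one column per feature named
#' `condition_channel_band`. A JSON sidecar (`<path>.json`) records the band
#' scheme, Welch parameters and PSD scaling convention when supplied.
#'
#' @param ft a [FeatureTable-class].
#' @param path CSV output path.
#' @param meta optional list written to the JSON sidecar.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(ft, path, meta = NULL) {
  cd <- as.data.frame(SummarizedExperiment::colData(ft))
  mat <- t(SummarizedExperiment::assay(ft, "bandpower"))
  out <- cbind(cd[, c("subject", "lag", "label", "group")], as.data.frame(mat))
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  metaCols <- c("subject", "lag", "label", "group")
  mat <- t(as.matrix(df[, setdiff(colnames(df), metaCols), drop = FALSE]))
  cd <- S4Vectors::DataFrame(df[, metaCols])
  rownames(cd) <- paste(cd$subject, cd$lag, sep = ".")
  colnames(mat) <- rownames(cd)
  rd <- featureIndex()
  rd <- rd[match(rownames(mat), rd$name), c("condition", "channel", "band")]
  rownames(rd) <- rownames(mat)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(bandpower = mat),
    rowData = S4Vectors::DataFrame(rd), colData = cd)
  methods::new("FeatureTable", se)
}
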