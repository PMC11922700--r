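#' @importFrom signal fir1 hamming
#' @importFrom zoo rollmax
NULL

# cache for FIR kernels keyed by (fs, low, high, n)
.firCache <- new.env(parent = emptyenv())

# symmetric (linear-phase) FIR applied with exact delay compensation =>
# zero-phase. Reflection padding absorbs edge transients.
applyFIRZeroPhase <- function(dat, h) {
  stopifnot(length(h) %% 2 == 1)
  half <- (length(h) - 1L) / 2L
  n <- ncol(dat)
  pad <- min(half, n - 1L)
  out <- dat
  for (ch in seq_len(nrow(dat))) {
    x <- dat[ch, ]
    # even mirror reflection: the pad keeps the signal's local mean (an odd /
    # point reflection would put a ~2*x[edge] pedestal under the long
    # high-pass kernel and bleed it into the block)
    xp <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
    y <- stats::convolve(xp, rev(h), type = "open")  # length n + 2*pad + len(h) - 1
    out[ch, ] <- y[(pad + half + 1):(pad + half + n)]
  }
  out
}

firKernel <- function(fs, low, high) {
  key <- paste(fs, low, high, sep = "_")
  if (!is.null(.firCache[[key]])) return(.firCache[[key]])
  # cascade: long Hamming high-pass (0.1 Hz one-sided transition) then a short
  # Hamming low-pass (10 Hz transition); both symmetric, hence zero-phase after
  # delay compensation
  nHigh <- 2L * round(3.3 * fs / (2 * low) / 2) # transition ~= low (one-sided)
  nLow <- 2L * round(3.3 * fs / 10 / 2)
  kern <- list(
    hp = signal::fir1(nHigh, low / (fs / 2), type = "high",
                      window = signal::hamming(nHigh + 1)),
    lp = signal::fir1(nLow, high / (fs / 2), type = "low",
                      window = signal::hamming(nLow + 1))
  )
  .firCache[[key]] <- kern
  kern
}

#' Zero-phase band-pass filter
#'
#' Filters every channel with a cascade of linear-phase Hamming-windowed FIR
#' filters (high-pass at `low`, low-pass at `high`) applied with exact group
#' delay compensation, so the composite response has zero phase. Attenuation
#' one octave beyond either corner exceeds 20 dB. On blocks shorter than the
#' high-pass kernel the kernel is truncated (with a warning) and the low-edge
#' transition widens accordingly.
#'
#' @param rec an [EEGRecording-class].
#' @param low,high corner frequencies in Hz (defaults 0.1 and 50).
#' @return The filtered [EEGRecording-class].
#' @export
bandpassFilter <- function(rec, low = 0.1, high = 50) {
  fs <- samplingRate(rec)
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2 (Nyquist)")
  }
  kern <- firKernel(fs, low, high)
  dat <- eegData(rec)
  n <- ncol(dat)
  hp <- kern$hp
  if (length(hp) > n) {
    warning("block shorter than the high-pass kernel; truncating kernel, ",
            "low-edge transition widens")
    half <- (n - (n %% 2 == 0)) %/% 2
    mid <- (length(hp) + 1L) / 2L
    hp <- hp[(mid - half):(mid + half)]
  }
  # low-pass first: the long high-pass kernel then sees a band-limited signal,
  # which keeps its reflection-padding edge transient small
  dat <- applyFIRZeroPhase(dat, kern$lp)
  dat <- applyFIRZeroPhase(dat, hp)
  methods::initialize(rec, data = dat)
}

#' Re-reference to the channel average
#'
#' Subtracts, at every sample, the instantaneous mean across channels, so the
#' channel mean is zero everywhere. Idempotent.
#'
#' @param rec an [EEGRecording-class] with at least 2 channels.
#' @return The re-referenced [EEGRecording-class].
#' @export
rereferenceAverage <- function(rec) {
  dat <- eegData(rec)
  if (nrow(dat) < 2) stop("average reference requires at least 2 channels")
  methods::initialize(rec, data = sweep(dat, 2, colMeans(dat)))
}

#' Remove ocular independent components by template match
#'
#' Decomposes the recording with FastICA (symmetric decorrelation, logcosh
#' contrast), correlates every mixing-column topography with the vertical and
#' horizontal eye-movement templates, zeroes components whose absolute spatial
#' correlation reaches the template threshold (at most `maxRemove`, best
#' matches first) and back-projects the rest. If ICA fails to converge the
#' recording is passed through unmodified and flagged in the report.
#'
#' @param rec an [EEGRecording-class], already filtered and average-referenced;
#'   at least ~60 s of signal is recommended for a stable unmixing.
#' @param templates an [ocularTemplates()] list.
#' @param maxRemove maximum number of components to remove (default 4).
#' @param nComp number of components; defaults to channels - 1 (the rank after
#'   average referencing).
#' @param seed seed for the ICA random initialisation.
#' @return List with `recording` (cleaned [EEGRecording-class]) and `report`
#'   (data.frame: component, matched template, absolute correlation, removed)
#'   plus logical `converged`.
#' @export
removeOcularICA <- function(rec, templates = ocularTemplates(rec@montage),
                            maxRemove = 4, nComp = NULL, seed = 1) {
  dat <- eegData(rec)
  nch <- nrow(dat)
  if (is.null(nComp)) nComp <- nch - 1L
  decim <- max(1L, ncol(dat) %/% 8000L)  # estimate unmixing on ~8k samples
  fit <- withSeed(deriveSeed(seed, 31),
                  fastICA(dat, nComp, estimateEvery = decim))
  A <- fit$A  # channels x components mixing topographies
  corV <- abs(apply(A, 2, stats::cor, y = templates$vertical))
  corH <- abs(apply(A, 2, stats::cor, y = templates$horizontal))
  best <- pmax(corV, corH)
  tpl <- ifelse(corV >= corH, "vertical", "horizontal")
  matched <- which(best >= templates$threshold)
  removed <- matched[order(best[matched], decreasing = TRUE)]
  removed <- removed[seq_len(min(length(removed), maxRemove))]
  # the decomposition is trustworthy for removal when the matched components
  # themselves reached a stable fixed point, even if the near-Gaussian
  # background subspace is still rotating (which a global criterion flags)
  if (!fit$converged && length(removed) &&
      max(fit$compDelta[removed]) >= 0.05) {
    warning("ICA did not converge on a template-matched component (final step ",
            signif(max(fit$compDelta[removed]), 2), " after ", fit$iterations,
            " iterations); recording passed through unmodified")
    return(list(recording = rec,
                report = data.frame(component = integer(), template = character(),
                                    correlation = numeric(), removed = logical()),
                converged = FALSE))
  }
  report <- data.frame(component = seq_len(ncol(A)), template = tpl,
                       correlation = best,
                       removed = seq_len(ncol(A)) %in% removed)
  S <- fit$S
  if (length(removed)) S[removed, ] <- 0
  clean <- A %*% S + fit$mean
  dimnames(clean) <- dimnames(dat)
  list(recording = methods::initialize(rec, data = clean),
       report = report, converged = TRUE)
}

#' Flag high-amplitude jumps by sliding-window peak-to-trough amplitude
#'
#' For every channel, computes the peak-to-trough amplitude in a sliding
#' window (stride 1 sample) and flags windows whose amplitude exceeds the
#' channel's mean window amplitude plus `sdMult` standard deviations. The
#' standard deviation defaults to that of the channel's samples
#' (`population = "signal"`): a short transient then cannot mask itself by
#' inflating the spread it is measured against, so a 15-SD rule actually fires
#' on isolated jumps. `population = "windows"` instead uses the SD of the
#' window-amplitude series itself. Flagged windows are expanded to their
#' covered samples, padded by `padSec` on each side (clipped at block edges),
#' and the union over channels is returned. Channels with a zero-variance
#' statistic flag nothing (with a warning).
#'
#' @param rec an [EEGRecording-class] or [CleanRecording-class].
#' @param windowSec sliding window length in seconds (default 0.5).
#' @param sdMult rejection threshold in standard deviations (default 15).
#' @param padSec padding added before and after flagged segments (default 0.5).
#' @param population `"signal"` (default) or `"windows"`: which spread the
#'   `sdMult` multiplies.
#' @return List with `mask` (logical per sample, TRUE = excluded) and
#'   `intervals` (data.frame of excluded spans in seconds).
#' @export
rejectJumps <- function(rec, windowSec = 0.5, sdMult = 15, padSec = 0.5,
                        population = c("signal", "windows")) {
  population <- match.arg(population)
  dat <- eegData(rec)
  fs <- samplingRate(rec)
  w <- round(windowSec * fs)
  if (w < 2) stop("window must span at least 2 samples")
  n <- ncol(dat)
  if (w > n) stop("window longer than the recording")
  pad <- round(padSec * fs)
  mask <- logical(n)
  zeroVar <- FALSE
  for (ch in seq_len(nrow(dat))) {
    x <- dat[ch, ]
    ptt <- zoo::rollmax(x, w) + zoo::rollmax(-x, w)  # max - min per window
    s <- if (population == "signal") stats::sd(x) else stats::sd(ptt)
    if (is.na(s) || s == 0) { zeroVar <- TRUE; next }
    bad <- which(ptt > mean(ptt) + sdMult * s)
    if (!length(bad)) next
    for (b in bad) {
      lo <- max(1L, b - pad)
      hi <- min(n, b + w - 1L + pad)
      mask[lo:hi] <- TRUE
    }
  }
  if (zeroVar) warning("zero-variance peak-to-trough series on >=1 channel; it flags nothing")
  list(mask = mask, intervals = maskToIntervals(mask, fs))
}

#' Preprocess a recording
#'
#' Applies, in fixed order, the full preprocessing chain: zero-phase band-pass
#' (0.1-50 Hz), average re-reference, ICA ocular-component removal by template
#' match, and sliding-window peak-to-trough jump rejection (computed on the
#' cleaned signal; the ocular step never alters the mask). Every step is
#' recorded in the provenance with its parameters.
#'
#' @param rec an [EEGRecording-class].
#' @param low,high band-pass corners in Hz.
#' @param templates ocular templates, see [ocularTemplates()].
#' @param maxRemove maximum ocular components removed.
#' @param windowSec,sdMult,padSec jump-rejection settings, see [rejectJumps()].
#' @param runICA set `FALSE` to skip ocular removal (e.g. artifact-free
#'   synthetic data).
#' @param seed seed for the ICA initialisation.
#' @return A [CleanRecording-class].
#' @export
preprocess <- function(rec, low = 0.1, high = 50,
                       templates = ocularTemplates(rec@montage),
                       maxRemove = 4, windowSec = 0.5, sdMult = 15,
                       padSec = 0.5, runICA = TRUE, seed = 1) {
  prov <- list()
  rec <- bandpassFilter(rec, low, high)
  prov <- c(prov, list(list(step = "bandpass", low = low, high = high,
                            realization = "zero-phase Hamming FIR cascade")))
  rec <- rereferenceAverage(rec)
  prov <- c(prov, list(list(step = "rereference", type = "average")))
  if (runICA) {
    ica <- removeOcularICA(rec, templates, maxRemove = maxRemove, seed = seed)
    rec <- ica$recording
    prov <- c(prov, list(list(step = "ica_ocular",
                              threshold = templates$threshold,
                              removed = which(ica$report$removed),
                              correlations = ica$report$correlation[ica$report$removed],
                              converged = ica$converged)))
  }
  rj <- rejectJumps(rec, windowSec, sdMult, padSec)
  prov <- c(prov, list(list(step = "reject_jumps", windowSec = windowSec,
                            sdMult = sdMult, padSec = padSec,
                            statistic = "per-channel over all sliding windows",
                            excluded_fraction = mean(rj$mask))))
  new("CleanRecording", data = eegData(rec), fs = samplingRate(rec),
      subject = rec@subject, group = rec@group, lag = rec@lag,
      condition = rec@condition, block = rec@block, montage = rec@montage,
      mask = rj$mask, provenance = prov)
}
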