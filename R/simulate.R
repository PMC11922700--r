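#' Specify pre/post spectral effects for a synthetic cohort
#'
#' The effect specification is the ground truth a synthetic cohort realises:
#' multiplicative band-power changes per session lag, an exercise effect
#' applied to every session recorded within an hour of an exercise bout, the
#' between-subject spread of log band power, and the artifact injection rates.
#' All factors of 1 and zero artifact rates give a null cohort.
#'
#' @param lagEffects named list (names are lags `"post1h"`/`"post24h"`), each a
#'   list of effects, each effect a list with `band` (scheme band name),
#'   `channels` (scalp-region name, `"all"`, or explicit labels) and `factor`
#'   (multiplicative band-power change, > 0).
#' @param exerciseEffect list of effects in the same form, applied to sessions
#'   recorded within 1 h after an exercise bout (the kicking group exercises
#'   before the pre session, both groups head the ball before the 1 h session).
#' @param subjectSd standard deviation of per-subject log band-power offsets.
#' @param blockSd standard deviation of per-block broadband log-gain jitter.
#' @param blinksPerMin,saccadesPerMin Poisson rates of ocular artifacts.
#' @param jumpsPerBlock fixed count of high-amplitude jump transients per block.
#' @return A list of class `"EffectSpec"`.
#' @export
#' @examples
#' # the demo 24 h impact signature: occipital alpha up 50%, frontal theta up 30%
#' effectSpec(lagEffects = list(post24h = list(
#'   list(band = "alpha", channels = "occipital", factor = 1.5),
#'   list(band = "theta", channels = "frontal", factor = 1.3))))
effectSpec <- function(lagEffects = list(), exerciseEffect = list(),
                       subjectSd = 0.25, blockSd = 0.05,
                       blinksPerMin = 8, saccadesPerMin = 4, jumpsPerBlock = 1) {
  checkEffects <- function(effs, where) {
    for (e in effs) {
      stopifnot(is.list(e), !is.null(e$band), !is.null(e$channels),
                is.numeric(e$factor))
      if (e$factor <= 0) stop("effect factors must be > 0 (", where, ")")
    }
  }
  if (length(lagEffects)) {
    bad <- setdiff(names(lagEffects), c("post1h", "post24h", "pre"))
    if (length(bad)) stop("unknown lag in lagEffects: ", paste(bad, collapse = ", "))
    for (lg in names(lagEffects)) checkEffects(lagEffects[[lg]], lg)
  }
  checkEffects(exerciseEffect, "exerciseEffect")
  stopifnot(subjectSd >= 0, blockSd >= 0, blinksPerMin >= 0,
            saccadesPerMin >= 0, jumpsPerBlock >= 0)
  structure(list(lagEffects = lagEffects, exerciseEffect = exerciseEffect,
                 subjectSd = subjectSd, blockSd = blockSd,
                 blinksPerMin = blinksPerMin, saccadesPerMin = saccadesPerMin,
                 jumpsPerBlock = round(jumpsPerBlock)),
            class = "EffectSpec")
}

#' A null effect specification with no artifacts
#'
#' All factors 1, zero artifact rates: the cohort is exchangeable across lags.
#' @param subjectSd,blockSd variability parameters, as in [effectSpec()].
#' @return An `"EffectSpec"` list.
#' @export
nullEffectSpec <- function(subjectSd = 0.25, blockSd = 0.05) {
  effectSpec(subjectSd = subjectSd, blockSd = blockSd,
             blinksPerMin = 0, saccadesPerMin = 0, jumpsPerBlock = 0)
}

#' Configure a synthetic EEG cohort
#'
#' Defaults mirror the study design: 36 subjects (half assigned to the kicking
#' group by alternation), three sessions (pre, 1 h post, 24 h post), 8 blocks
#' of 2.5 min per session cycling twice through the four eyes-by-posture
#' conditions, 32 channels at 512 Hz. The background spectrum is 1/f^beta
#' broadband noise plus posterior-weighted alpha and central beta oscillators;
#' eyes-closed blocks multiply the alpha oscillator by `alphaBoostClosed`.
#'
#' @param nSubjects number of subjects (>= 2; alternating group assignment).
#' @param fs sampling rate in Hz.
#' @param blockSec block duration in seconds (default 150 = 2.5 min).
#' @param montage electrode montage data.frame.
#' @param effect an [effectSpec()].
#' @param background list with `scale` (uV^2/Hz at 1 Hz), `exponent` (1/f
#'   slope), `alphaAmp`, `alphaFreq`, `alphaWidth`, `betaAmp`, `betaFreq`,
#'   `betaWidth` (oscillator bump amplitudes in uV^2/Hz, centres/widths in Hz).
#' @param alphaBoostClosed multiplicative alpha-oscillator gain when eyes closed.
#' @param lags which session lags to generate.
#' @param seed master seed; fixed seed implies byte-identical cohorts.
#' @return A list of class `"CohortConfig"`.
#' @export
cohortConfig <- function(nSubjects = 36, fs = 512, blockSec = 150,
                         montage = montage1010(), effect = effectSpec(),
                         background = list(scale = 10, exponent = 1.0,
                                           alphaAmp = 15, alphaFreq = 10,
                                           alphaWidth = 1, betaAmp = 3,
                                           betaFreq = 20, betaWidth = 2),
                         alphaBoostClosed = 2, lags = VALID_LAGS, seed = 1) {
  stopifnot(nSubjects >= 2, fs > 0, blockSec > 0,
            all(lags %in% VALID_LAGS), inherits(effect, "EffectSpec"))
  structure(list(nSubjects = as.integer(nSubjects), fs = fs,
                 blockSec = blockSec, montage = montage, effect = effect,
                 background = background, alphaBoostClosed = alphaBoostClosed,
                 lags = lags, seed = as.integer(seed)),
            class = "CohortConfig")
}

# lags recorded within 1 h of an exercise bout, by group: the kicking group
# exercises (kicking task) right before the pre session; both groups head the
# ball 1 h before the post1h session; nobody exercises before post24h.
exercisedLags <- function(group) {
  if (identical(group, "kicking")) c("pre", "post1h") else "post1h"
}

# per-subject multiplicative band-power offsets (lognormal, one per band)
drawSubjectOffsets <- function(config, subjectIndex) {
  bands <- names(bandScheme())
  withSeed(deriveSeed(config$seed, 7, subjectIndex), {
    offs <- exp(stats::rnorm(length(bands), 0, config$effect$subjectSd))
  })
  names(offs) <- bands
  offs
}

# one-sided target PSD, channels x frequencies, for a given block context
targetPSD <- function(config, freqs, group, lag, condition, offsets,
                      blockGain = 1) {
  bg <- config$background
  m <- config$montage
  nch <- nrow(m)
  f <- pmax(freqs, 0.5)
  broadband <- bg$scale * f^(-bg$exponent)
  alphaBump <- bg$alphaAmp * exp(-(freqs - bg$alphaFreq)^2 / (2 * bg$alphaWidth^2))
  betaBump <- bg$betaAmp * exp(-(freqs - bg$betaFreq)^2 / (2 * bg$betaWidth^2))
  # spatial gradients: alpha posterior-dominant, beta central-dominant
  wAlpha <- 0.3 + 0.7 * (1 - m$y) / 2
  wBeta <- 0.5 + 0.5 * (1 - abs(m$y))
  eyesClosed <- condition %in% c("ec_sit", "ec_stand")
  aGain <- if (eyesClosed) config$alphaBoostClosed else 1
  S <- outer(rep(1, nch), broadband) +
    outer(wAlpha, alphaBump) * aGain +
    outer(wBeta, betaBump)
  dimnames(S) <- NULL
  scheme <- bandScheme()
  bandIdx <- lapply(scheme, function(b) which(freqs >= b[1] & freqs < b[2]))
  # per-subject band offsets (all channels)
  for (b in names(scheme)) {
    S[, bandIdx[[b]]] <- S[, bandIdx[[b]]] * offsets[[b]]
  }
  applyEffects <- function(S, effs) {
    for (e in effs) {
      ch <- match(channelGroup(m, e$channels), m$label)
      S[ch, bandIdx[[e$band]]] <- S[ch, bandIdx[[e$band]]] * e$factor
    }
    S
  }
  le <- config$effect$lagEffects[[lag]]
  if (!is.null(le)) S <- applyEffects(S, le)
  if (lag %in% exercisedLags(group) && length(config$effect$exerciseEffect)) {
    S <- applyEffects(S, config$effect$exerciseEffect)
  }
  S * blockGain
}

# synthesize a real signal (channels x n) whose expected one-sided PSD is S.
# Two real channels are packed into the real/imaginary parts of each complex
# inverse FFT (both spectra are Hermitian, so ifft(Xa + i*Xb) = a + i*b).
synthFromPSD <- function(S, fs, n) {
  nch <- nrow(S)
  nf <- ncol(S)                       # floor(n/2) + 1 frequencies incl. DC
  amp <- sqrt(S * fs * n / 2)
  z <- matrix(complex(real = stats::rnorm(nch * nf), imaginary = stats::rnorm(nch * nf)),
              nch, nf) / sqrt(2)
  Z <- amp * z
  Z[, 1] <- 0                         # no DC
  if (n %% 2 == 0) Z[, nf] <- 0       # Nyquist outside all bands
  nPair <- (nch + 1L) %/% 2L
  X <- matrix(0i, n, nPair)
  for (p in seq_len(nPair)) {
    a <- 2L * p - 1L
    Za <- Z[a, ]
    Xa <- complex(n)
    Xa[seq_len(nf)] <- Za
    Xa[n:(n - nf + 2)] <- Conj(Za[2:nf])
    if (2L * p <= nch) {
      Zb <- Z[2L * p, ]
      Xb <- complex(n)
      Xb[seq_len(nf)] <- Zb
      Xb[n:(n - nf + 2)] <- Conj(Zb[2:nf])
      X[, p] <- Xa + 1i * Xb
    } else {
      X[, p] <- Xa
    }
  }
  Y <- stats::mvfft(X, inverse = TRUE) / n
  out <- matrix(0, nch, n)
  for (p in seq_len(nPair)) {
    out[2L * p - 1L, ] <- Re(Y[, p])
    if (2L * p <= nch) out[2L * p, ] <- Im(Y[, p])
  }
  out
}

halfCosinePulse <- function(nSamples) sin(pi * seq_len(nSamples) / (nSamples + 1))

rampedStep <- function(nSamples, fs, rampSec = 0.02) {
  r <- max(2L, round(rampSec * fs))
  r <- min(r, floor(nSamples / 2))
  up <- (1 - cos(pi * seq_len(r) / r)) / 2
  c(up, rep(1, nSamples - 2 * r), rev(up))
}

#' Generate one synthetic EEG block
#'
#' Synthesises a [EEGRecording-class] whose expected Welch band powers equal
#' the configured background spectrum times the subject's band offsets, the
#' eyes-closed alpha boost, and the lag/exercise effect factors for that
#' subject's group, then injects Poisson-placed blink and saccade artifacts
#' with stereotyped frontal topographies plus the configured number of
#' high-amplitude jump transients at known indices.
#'
#' @param config a [cohortConfig()].
#' @param subject subject identifier string.
#' @param lag session lag (`"pre"`, `"post1h"`, `"post24h"`).
#' @param condition one of the four eyes-by-posture states.
#' @param block block index (1..8).
#' @param group `"kicking"` or `"non_kicking"`.
#' @param offsets per-band subject offsets (drawn once per subject); if `NULL`
#'   they are derived from the subject name hash for stand-alone use.
#' @param seed block seed; if `NULL`, derived from the config seed and the
#'   block context.
#' @return List with `recording` (an [EEGRecording-class]) and `artifacts`
#'   (data.frame of injected artifacts: `type`, `channel`, `start`, `end`
#'   sample indices, `amplitude`).
#' @export
generateBlock <- function(config, subject = "S01", lag = "pre",
                          condition = "eo_sit", block = 1L,
                          group = "non_kicking", offsets = NULL, seed = NULL) {
  stopifnot(inherits(config, "CohortConfig"))
  if (!lag %in% VALID_LAGS) {
    stop("invalid lag '", lag, "'; expected one of ", paste(VALID_LAGS, collapse = ", "))
  }
  if (!condition %in% VALID_CONDITIONS) {
    stop("invalid condition '", condition, "'; expected one of ",
         paste(VALID_CONDITIONS, collapse = ", "))
  }
  stopifnot(group %in% VALID_GROUPS)
  if (is.null(offsets)) {
    offsets <- drawSubjectOffsets(config, sum(utf8ToInt(subject)))
  }
  if (is.null(seed)) {
    seed <- deriveSeed(config$seed, sum(utf8ToInt(subject)),
                       match(lag, VALID_LAGS), match(condition, VALID_CONDITIONS),
                       block)
  }
  fs <- config$fs
  n <- round(config$blockSec * fs)
  eff <- config$effect
  withSeed(seed, {
    blockGain <- exp(stats::rnorm(1, 0, eff$blockSd))
    freqs <- (0:(n %/% 2)) * fs / n
    S <- targetPSD(config, freqs, group, lag, condition, offsets, blockGain)
    dat <- synthFromPSD(S, fs, n)
    arts <- data.frame(type = character(), channel = character(),
                       start = integer(), end = integer(),
                       amplitude = numeric(), stringsAsFactors = FALSE)
    templates <- ocularTemplates(config$montage)
    minutes <- config$blockSec / 60
    addArtifact <- function(type, spatial, pulse, ampl) {
      dur <- length(pulse)
      t0 <- sample.int(max(1L, n - dur - as.integer(fs)), 1) + as.integer(fs / 2)
      t0 <- max(1L, min(t0, n - dur + 1L))
      idx <- t0:(t0 + dur - 1)
      dat[, idx] <<- dat[, idx] + outer(spatial, pulse) * ampl
      peak <- which.max(abs(spatial))
      arts <<- rbind(arts, data.frame(
        type = type, channel = config$montage$label[peak],
        start = t0, end = t0 + dur - 1L, amplitude = ampl,
        stringsAsFactors = FALSE))
    }
    nBlinks <- stats::rpois(1, eff$blinksPerMin * minutes)
    vTpl <- templates$vertical / max(templates$vertical)
    for (i in seq_len(nBlinks)) {
      addArtifact("blink", vTpl, halfCosinePulse(round(0.3 * fs)),
                  stats::rnorm(1, 100, 15))
    }
    nSacc <- stats::rpois(1, eff$saccadesPerMin * minutes)
    hTpl <- templates$horizontal / max(abs(templates$horizontal))
    for (i in seq_len(nSacc)) {
      addArtifact("saccade", hTpl, rampedStep(round(0.4 * fs), fs),
                  sample(c(-1, 1), 1) * stats::rnorm(1, 40, 8))
    }
    for (i in seq_len(eff$jumpsPerBlock)) {
      ch <- sample.int(nrow(config$montage), 1)
      dur <- round(stats::runif(1, 0.05, 0.2) * fs)
      t0 <- sample.int(max(1L, n - dur - as.integer(fs)), 1) + as.integer(fs / 2)
      t0 <- max(1L, min(t0, n - dur + 1L))
      amp <- sample(c(-1, 1), 1) * 40 * stats::sd(dat[ch, ])
      dat[ch, t0:(t0 + dur - 1)] <- dat[ch, t0:(t0 + dur - 1)] + amp
      arts <- rbind(arts, data.frame(
        type = "jump", channel = config$montage$label[ch],
        start = t0, end = t0 + dur - 1L, amplitude = amp,
        stringsAsFactors = FALSE))
    }
  })
  rec <- EEGRecording(dat, fs = fs, subject = subject, group = group,
                      lag = lag, condition = condition, block = block,
                      montage = config$montage)
  list(recording = rec, artifacts = arts)
}

#' Generate a full synthetic cohort
#'
#' Materialises every block (`nSubjects` x `length(lags)` x 8) as
#' [EEGRecording-class] objects plus a ground-truth manifest listing every
#' injected artifact and the realised per-subject band offsets. Reproducible:
#' the same config (including seed) yields an identical cohort. For large
#' configurations prefer the streaming [cohortFeatureVectors()], which never
#' holds raw signals for more than one block.
#'
#' @param config a [cohortConfig()].
#' @return List with `recordings` (list of [EEGRecording-class]) and
#'   `manifest` (list: `subjects` data.frame, `offsets` matrix subjects x
#'   bands, `artifacts` data.frame with block context, `config`).
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  walkCohort(config, function(blk, art) blk)
}

# internal iterator: calls fn(recording, artifacts) per block, assembles
# recordings + manifest; fn may return NULL to drop the raw recording.
walkCohort <- function(config, fn) {
  subjects <- sprintf("S%02d", seq_len(config$nSubjects))
  groups <- ifelse(seq_len(config$nSubjects) %% 2 == 1, "kicking", "non_kicking")
  offsets <- t(vapply(seq_len(config$nSubjects),
                      function(i) drawSubjectOffsets(config, i),
                      numeric(length(bandScheme()))))
  rownames(offsets) <- subjects
  recordings <- list()
  artList <- list()
  out <- list()
  for (si in seq_along(subjects)) {
    for (li in seq_along(config$lags)) {
      lag <- config$lags[li]
      for (bi in 1:8) {
        cond <- BLOCK_ORDER[bi]
        seed <- deriveSeed(config$seed, si, match(lag, VALID_LAGS), bi)
        blk <- generateBlock(config, subjects[si], lag, cond, bi,
                             group = groups[si], offsets = offsets[si, ],
                             seed = seed)
        if (nrow(blk$artifacts)) {
          artList[[length(artList) + 1L]] <- cbind(
            data.frame(subject = subjects[si], group = groups[si], lag = lag,
                       condition = cond, block = bi, stringsAsFactors = FALSE),
            blk$artifacts)
        }
        res <- fn(blk$recording, blk$artifacts)
        if (!is.null(res)) out[[length(out) + 1L]] <- res
      }
    }
  }
  artifacts <- if (length(artList)) do.call(rbind, artList) else
    data.frame(subject = character(), group = character(), lag = character(),
               condition = character(), block = integer(), type = character(),
               channel = character(), start = integer(), end = integer(),
               amplitude = numeric(), stringsAsFactors = FALSE)
  list(recordings = out,
       manifest = list(
         subjects = data.frame(subject = subjects, group = groups,
                               stringsAsFactors = FALSE),
         offsets = offsets, artifacts = artifacts, config = config))
}
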