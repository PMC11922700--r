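# Independent oracles and fixture builders shared across the test files.

# brute-force sliding-window peak-to-trough rejection: recomputes every window
# amplitude directly and applies the same flag/pad/union rule as rejectJumps()
bruteForceJumpMask <- function(dat, fs, windowSec = 0.5, sdMult = 15,
                               padSec = 0.5, population = "signal") {
  w <- round(windowSec * fs)
  n <- ncol(dat)
  pad <- round(padSec * fs)
  mask <- logical(n)
  for (ch in seq_len(nrow(dat))) {
    x <- dat[ch, ]
    ptt <- vapply(seq_len(n - w + 1L), function(i) {
      seg <- x[i:(i + w - 1L)]
      max(seg) - min(seg)
    }, 0)
    s <- if (population == "signal") stats::sd(x) else stats::sd(ptt)
    if (is.na(s) || s == 0) next
    for (b in which(ptt > mean(ptt) + sdMult * s)) {
      mask[max(1L, b - pad):min(n, b + w - 1L + pad)] <- TRUE
    }
  }
  mask
}

# direct (definition-level) Welch PSD: explicit loop over windows, no masking
directWelchPSD <- function(x, fs, nfft = 512, overlapSec = 0.5) {
  step <- nfft - round(overlapSec * fs)
  starts <- seq(1, length(x) - nfft + 1, by = step)
  k <- seq_len(nfft) - 1
  w <- 0.5 - 0.5 * cos(2 * pi * k / (nfft - 1))
  nf <- nfft %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    X <- stats::fft(x[s:(s + nfft - 1)] * w)[1:nf]
    P <- Mod(X)^2 / (fs * sum(w^2))
    P[2:(nf - 1)] <- 2 * P[2:(nf - 1)]
    acc <- acc + P
  }
  acc / length(starts)
}

# synthetic feature table built directly in feature space (fast path for
# classifier tests): post rows of the first `nEffect` features are shifted by
# `effectSize` (in SD units). With `exact = TRUE` the effect features carry no
# within-class noise (an exactly separable table: with histogram split finding
# the cut hugs the training positives' minimum, so any continuous within-class
# noise leaves an irreducible ~1/(n+1) boundary error per held-out positive
# regardless of the shift size; the noise-free fixture tests the
# "separable => near-perfect" contract itself)
makeToyFeatureTable <- function(nSubjects = 10, nFeatures = 24, effectSize = 0,
                                nEffect = 3, seed = 1, exact = FALSE) {
  set.seed(seed)
  nObs <- 2L * nSubjects
  mat <- matrix(rnorm(nFeatures * nObs), nFeatures, nObs)
  lag <- rep(c("pre", "post24h"), nSubjects)
  if (exact) {
    mat[seq_len(nEffect), ] <- 0
  }
  mat[seq_len(nEffect), lag == "post24h"] <-
    mat[seq_len(nEffect), lag == "post24h"] + effectSize
  subject <- rep(sprintf("S%02d", seq_len(nSubjects)), each = 2)
  cd <- S4Vectors::DataFrame(
    subject = subject, lag = lag,
    label = ifelse(lag == "pre", "baseline", "post_impact"),
    group = rep(rep(c("kicking", "non_kicking"), length.out = nSubjects),
                each = 2))
  rownames(cd) <- paste(subject, lag, sep = ".")
  colnames(mat) <- rownames(cd)
  rownames(mat) <- sprintf("f%03d", seq_len(nFeatures))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(bandpower = mat), colData = cd)
  methods::new("FeatureTable", se)
}

# default mid-range hyperparameters for direct groupedCV calls
toyHyperParams <- function(nFeatures = 24) {
  list(max_depth = 3L, reg_alpha = 1e-3, reg_lambda = 1, subsample = 0.9,
       colsample_bytree = 0.8, eta = 0.3,
       n_selected_features = min(16L, nFeatures))
}

# a small artifact-free cohort config for feature-level tests
quickConfig <- function(nSubjects = 4, blockSec = 10, effect = nullEffectSpec(),
                        lags = c("pre", "post24h"), seed = 1, ...) {
  cohortConfig(nSubjects = nSubjects, blockSec = blockSec, effect = effect,
               lags = lags, seed = seed, ...)
}
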