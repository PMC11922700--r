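sineMatrix <- function(freq, sec, fs = 512, nch = 2, amp = 1) {
  t <- seq(1 / fs, sec, by = 1 / fs)
  matrix(rep(amp * sin(2 * pi * freq * t), nch), nch, byrow = TRUE)
}

test_that("a 1 s window is reported for NFFT = 512 at 512 Hz", {
  expect_equal(welchParams(nfft = 512, fs = 512)$windowSec, 1)
})

test_that("a pure alpha tone concentrates in alpha and satisfies Parseval", {
  dat <- sineMatrix(10, sec = 150)
  bp <- welchBandPower(dat, fs = 512)
  scheme <- bandScheme()
  widths <- vapply(scheme, diff, 0)
  tot <- sum(bp$power[1, ] * widths)          # integral over 1-50 Hz
  expect_equal(tot, 0.5, tolerance = 0.05)    # variance of a unit sinusoid
  expect_gte(bp$power[1, "alpha"] * widths["alpha"] / tot, 0.95)
})

test_that("white-noise band powers reconstruct the in-band variance", {
  set.seed(2)
  fs <- 512
  dat <- matrix(rnorm(2 * 120 * fs), 2)
  bp <- welchBandPower(dat, fs = fs)
  widths <- vapply(bandScheme(), diff, 0)
  inband <- sum(bp$power[1, ] * widths)
  expect_equal(inband, 49 / 256, tolerance = 0.05)  # sigma^2 * (50-1)/Nyquist
})

test_that("Welch agrees with a direct periodogram average to 1e-6", {
  set.seed(5)
  x <- rnorm(20 * 512)
  bp <- welchBandPower(rbind(x, x), fs = 512)
  want <- directWelchPSD(x, fs = 512)
  expect_lt(max(abs(bp$psd[1, ] - want) / max(want)), 1e-6)
})

test_that("band power scales as amplitude squared and permutes with channels", {
  set.seed(6)
  dat <- matrix(rnorm(3 * 10 * 512), 3)
  b1 <- welchBandPower(dat, fs = 512)$power
  b2 <- welchBandPower(3 * dat, fs = 512)$power
  expect_equal(b2, 9 * b1, tolerance = 1e-12)
  perm <- c(3, 1, 2)
  bp <- welchBandPower(dat[perm, ], fs = 512)$power
  expect_equal(bp, b1[perm, ], tolerance = 1e-12)
})

test_that("masked samples drop exactly the windows that touch them", {
  set.seed(7)
  fs <- 512
  dat <- matrix(rnorm(2 * 10 * fs), 2)
  full <- welchBandPower(dat, fs = fs)
  expect_equal(full$nWindows, 19)
  mask <- rep(FALSE, ncol(dat)); mask[2561] <- TRUE  # touches windows at 2305, 2561
  part <- welchBandPower(dat, fs = fs, mask = mask)
  expect_equal(part$nWindows, 17)
  allmask <- rep(TRUE, ncol(dat))
  empty <- welchBandPower(dat, fs = fs, mask = allmask)
  expect_true(empty$missing)
  expect_equal(empty$nWindows, 0)
  expect_true(all(is.na(empty$power)))
})

test_that("session features average like-condition blocks arithmetically", {
  cc <- quickConfig(nSubjects = 2, blockSec = 6, lags = "pre")
  mkBlock <- function(cond, block, scale = 1) {
    b <- generateBlock(cc, "S01", "pre", cond, block, "non_kicking", seed = 8)
    methods::initialize(b$recording, data = eegData(b$recording) * scale)
  }
  b1 <- mkBlock("eo_sit", 1)
  b3 <- mkBlock("eo_sit", 5, scale = sqrt(3))     # powers x3
  sf <- sessionFeatures(list(b1, b3))
  one <- sessionFeatures(list(b1, b1))
  sel <- startsWith(names(sf$values), "eo_sit")
  expect_equal(sf$values[sel], 2 * one$values[sel], tolerance = 1e-10)
  expect_false(sf$missing["eo_sit"])
  expect_true(sf$missing["ec_stand"])
  expect_error(sessionFeatures(list(b1, generateBlock(cc, "S02", "pre",
    "eo_sit", 1, "kicking")$recording)), "single subject")
})

test_that("a fully rejected block leaves the surviving block's features", {
  cc <- quickConfig(nSubjects = 2, blockSec = 6, lags = "pre")
  b1 <- generateBlock(cc, "S01", "pre", "ec_sit", 2, "non_kicking", seed = 1)$recording
  b2 <- generateBlock(cc, "S01", "pre", "ec_sit", 6, "non_kicking", seed = 2)$recording
  dead <- new("CleanRecording", data = eegData(b2), fs = samplingRate(b2),
              subject = "S01", group = "non_kicking", lag = "pre",
              condition = "ec_sit", block = 6L, montage = b2@montage,
              mask = rep(TRUE, ncol(eegData(b2))),
              provenance = list(list(step = "mask_all")))
  sf <- sessionFeatures(list(b1, dead))
  alone <- sessionFeatures(list(b1))
  sel <- startsWith(names(sf$values), "ec_sit")
  expect_equal(sf$values[sel], alone$values[sel])
  expect_equal(sf$nBlocks[["ec_sit"]], 1L)
})

test_that("feature tables have 2 rows per complete subject and binary labels", {
  cc <- quickConfig(nSubjects = 3, blockSec = 4)
  fv <- cohortFeatureVectors(cc)
  ft <- assembleFeatureTable(fv$sessions, c("pre", "post24h"))
  expect_s4_class(ft, "FeatureTable")
  expect_equal(dim(ft), c(768, 6))
  cd <- SummarizedExperiment::colData(ft)
  expect_setequal(unique(cd$label), c("baseline", "post_impact"))
  expect_true(all(table(cd$subject) == 2))
  # dropping one subject's post sessions loses that subject with a warning
  keep <- Filter(function(s) !(s$subject == "S02" && s$lag == "post24h"),
                 fv$sessions)
  expect_warning(ft2 <- assembleFeatureTable(keep, c("pre", "post24h")),
                 "missing a lag")
  expect_equal(ncol(ft2), 4)
})

test_that("feature tables round-trip through CSV", {
  ft <- makeToyFeatureTable(nSubjects = 4, nFeatures = 12)
  path <- tempfile(fileext = ".csv")
  writeFeatureTable(ft, path, meta = list(scaling = "density"))
  expect_true(file.exists(paste0(path, ".json")))
  back <- readFeatureTable(path)
  expect_equal(SummarizedExperiment::assay(back, "bandpower"),
               SummarizedExperiment::assay(ft, "bandpower"))
  expect_equal(as.data.frame(SummarizedExperiment::colData(back)),
               as.data.frame(SummarizedExperiment::colData(ft)))
})
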