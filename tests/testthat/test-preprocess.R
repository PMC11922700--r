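sinRecording <- function(freq, sec = 20, fs = 512, nch = 32, amp = 1) {
  t <- seq(1 / fs, sec, by = 1 / fs)
  EEGRecording(matrix(rep(amp * sin(2 * pi * freq * t), nch), nch, byrow = TRUE),
               fs = fs)
}

test_that("band-pass passes in-band and rejects out-of-band sinusoids", {
  rms <- function(r) sqrt(mean(eegData(r)[1, ]^2))
  expect_lt(rms(bandpassFilter(sinRecording(60))) / sqrt(0.5), 0.10)
  expect_equal(rms(bandpassFilter(sinRecording(10))) / sqrt(0.5), 1,
               tolerance = 0.05)
  zero <- sinRecording(10, amp = 0)
  expect_equal(eegData(bandpassFilter(zero)), eegData(zero))
  expect_error(bandpassFilter(sinRecording(10), low = 10, high = 300),
               "Nyquist")
  expect_error(bandpassFilter(sinRecording(10), low = 50, high = 10))
})

test_that("average reference zeroes the channel mean and is idempotent", {
  cc <- quickConfig(blockSec = 2)
  rec <- generateBlock(cc, "S01", "pre", "eo_sit", 1, "non_kicking")$recording
  ref <- rereferenceAverage(rec)
  expect_lt(max(abs(colMeans(eegData(ref)))), 1e-10)
  expect_equal(eegData(rereferenceAverage(ref)), eegData(ref))
  # two-channel closed form: +/-(a-b)/2
  m2 <- montage1010()[1:2, ]
  a <- sin(seq(0, 10, length.out = 1000)); b <- cos(seq(0, 10, length.out = 1000))
  r2 <- EEGRecording(rbind(a, b), fs = 100, montage = m2)
  out <- eegData(rereferenceAverage(r2))
  expect_equal(out[1, ], (a - b) / 2, ignore_attr = TRUE)
  expect_equal(out[2, ], (b - a) / 2, ignore_attr = TRUE)
  r1 <- EEGRecording(rbind(a), fs = 100, montage = m2[1, ])
  expect_error(rereferenceAverage(r1), "at least 2 channels")
})

test_that("jump rejection matches the brute-force oracle mask-for-mask", {
  cc <- quickConfig(blockSec = 8, effect = effectSpec(
    blinksPerMin = 0, saccadesPerMin = 0, jumpsPerBlock = 2))
  for (seed in 1:4) {
    rec <- generateBlock(cc, "S01", "pre", "eo_sit", 1, "non_kicking",
                         seed = seed)$recording
    got <- rejectJumps(rec)
    want <- bruteForceJumpMask(eegData(rec), samplingRate(rec))
    expect_identical(got$mask, want)
  }
  # and under the windows-population variant
  rec <- generateBlock(cc, "S01", "pre", "eo_sit", 1, "non_kicking",
                       seed = 9)$recording
  got <- rejectJumps(rec, population = "windows")
  want <- bruteForceJumpMask(eegData(rec), samplingRate(rec),
                             population = "windows")
  expect_identical(got$mask, want)
})

test_that("an isolated large spike is excluded with the stated padding, and nothing else", {
  fs <- 512
  set.seed(4)
  n <- 60 * fs
  dat <- matrix(rnorm(4 * n), 4, n)
  m <- montage1010()[1:4, ]
  spike <- 50  # x background SD, 200 ms, centred at t = 30 s
  idx <- (30 * fs - 0.1 * fs):(30 * fs + 0.1 * fs - 1)
  dat[2, idx] <- dat[2, idx] + spike
  rec <- EEGRecording(dat, fs = fs, montage = m)
  rj <- rejectJumps(rec)
  expect_equal(nrow(rj$intervals), 1)
  # spike span, widened by the window reach (0.5 s) and the 0.5 s padding
  expect_lt(rj$intervals$start_s, 30 - 0.1)
  expect_gt(rj$intervals$start_s, 30 - 0.1 - 0.5 - 0.5 - 0.01)
  expect_gt(rj$intervals$end_s, 30 + 0.1)
  expect_lt(rj$intervals$end_s, 30 + 0.1 + 0.5 + 0.5 + 0.01)
})

test_that("clean Gaussian noise keeps exclusions rare and constants flag nothing", {
  fs <- 512
  set.seed(11)
  m <- montage1010()[1:8, ]
  rec <- EEGRecording(matrix(rnorm(8 * 20 * fs), 8), fs = fs, montage = m)
  expect_lt(mean(rejectJumps(rec)$mask), 0.01)
  zrec <- EEGRecording(matrix(0, 8, 20 * fs), fs = fs, montage = m)
  expect_warning(rj <- rejectJumps(zrec), "zero-variance")
  expect_false(any(rj$mask))
})

test_that("preprocess applies the fixed step order and records provenance", {
  cc <- quickConfig(blockSec = 60, effect = effectSpec(
    blinksPerMin = 0, saccadesPerMin = 0, jumpsPerBlock = 1))
  rec <- generateBlock(cc, "S01", "pre", "eo_sit", 1, "non_kicking",
                       seed = 3)$recording
  clean <- preprocess(rec, runICA = FALSE)
  steps <- vapply(provenance(clean), `[[`, "", "step")
  expect_equal(steps, c("bandpass", "rereference", "reject_jumps"))
  expect_s4_class(clean, "CleanRecording")
  expect_length(rejectionMask(clean), ncol(eegData(clean)))
  # average reference holds on the cleaned signal
  expect_lt(max(abs(colMeans(eegData(clean)))), 1e-8)
  # the jump was flagged on the cleaned signal
  expect_gt(sum(rejectionMask(clean)), 0)
  iv <- maskIntervals(clean)
  expect_true(all(iv$end_s > iv$start_s))
})
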