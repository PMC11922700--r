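test_that("block generation is byte-deterministic given a seed", {
  cc <- quickConfig()
  b1 <- generateBlock(cc, "S01", "pre", "ec_sit", 1, "non_kicking", seed = 5)
  b2 <- generateBlock(cc, "S01", "pre", "ec_sit", 1, "non_kicking", seed = 5)
  expect_identical(eegData(b1$recording), eegData(b2$recording))
  expect_identical(b1$artifacts, b2$artifacts)
  b3 <- generateBlock(cc, "S01", "pre", "ec_sit", 1, "non_kicking", seed = 6)
  expect_false(identical(eegData(b1$recording), eegData(b3$recording)))
})

test_that("block dimensions, units and metadata honour the design", {
  cc <- quickConfig(blockSec = 4)
  blk <- generateBlock(cc, "S07", "post1h", "eo_stand", 3, "kicking")
  rec <- blk$recording
  expect_equal(dim(eegData(rec)), c(32, 4 * 512))
  expect_equal(samplingRate(rec), 512)
  expect_equal(sessionLag(rec), "post1h")
  expect_error(generateBlock(cc, "S01", "post2h", "eo_sit"), "invalid lag")
  expect_error(generateBlock(cc, "S01", "pre", "eyes_shut"), "invalid condition")
})

test_that("zero artifact rates give an empty ground-truth artifact list", {
  cc <- quickConfig(blockSec = 4)
  blk <- generateBlock(cc, "S01", "pre", "eo_sit", 1, "non_kicking", seed = 2)
  expect_equal(nrow(blk$artifacts), 0)
  ccArt <- quickConfig(blockSec = 4, effect = effectSpec(
    blinksPerMin = 30, saccadesPerMin = 30, jumpsPerBlock = 2))
  blk2 <- generateBlock(ccArt, "S01", "pre", "eo_sit", 1, "non_kicking", seed = 2)
  expect_gt(nrow(blk2$artifacts), 0)
  expect_equal(sum(blk2$artifacts$type == "jump"), 2)
  expect_true(all(blk2$artifacts$end <= ncol(eegData(blk2$recording))))
})

test_that("cohort counts follow the subjects x lags x blocks design", {
  cc <- quickConfig(nSubjects = 2, blockSec = 2, lags = c("pre", "post1h", "post24h"))
  coh <- generateCohort(cc)
  expect_length(coh$recordings, 2 * 3 * 8)
  expect_setequal(unique(coh$manifest$subjects$group), c("kicking", "non_kicking"))
  # same seed -> identical manifest and data
  coh2 <- generateCohort(cc)
  expect_identical(coh$manifest$artifacts, coh2$manifest$artifacts)
  expect_identical(eegData(coh$recordings[[5]]), eegData(coh2$recordings[[5]]))
})

test_that("an injected band factor is realised in mean Welch band power", {
  eff <- effectSpec(lagEffects = list(post24h = list(
    list(band = "alpha", channels = "occipital", factor = 1.5))),
    subjectSd = 0, blockSd = 0,
    blinksPerMin = 0, saccadesPerMin = 0, jumpsPerBlock = 0)
  cc <- quickConfig(blockSec = 8, effect = eff)
  power <- function(lag, i) {
    blk <- generateBlock(cc, "S01", lag, "eo_sit", 1, "non_kicking",
                         seed = deriveSeed(99, i, match(lag, c("pre", "post24h"))))
    welchBandPower(blk$recording)$power
  }
  pre <- sapply(1:50, function(i) power("pre", i)["Oz", "alpha"])
  post <- sapply(1:50, function(i) power("post24h", i)["Oz", "alpha"])
  expect_equal(mean(post) / mean(pre), 1.5, tolerance = 0.1)
  # untouched channel group stays at factor 1
  preF <- sapply(1:50, function(i) power("pre", i)["Fz", "alpha"])
  postF <- sapply(1:50, function(i) power("post24h", i)["Fz", "alpha"])
  expect_equal(mean(postF) / mean(preF), 1.0, tolerance = 0.1)
})

test_that("null cohorts are exchangeable across lags", {
  cc <- quickConfig(nSubjects = 2, blockSec = 8,
                    effect = nullEffectSpec(subjectSd = 0, blockSd = 0))
  alphaAt <- function(lag, i) {
    blk <- generateBlock(cc, "S01", lag, "eo_sit", 1, "non_kicking",
                         seed = deriveSeed(3, i, match(lag, c("pre", "post1h"))))
    welchBandPower(blk$recording)$power["Oz", "alpha"]
  }
  pre <- sapply(1:60, alphaAt, lag = "pre")
  post <- sapply(1:60, alphaAt, lag = "post1h")
  expect_gt(stats::ks.test(pre, post)$p.value, 0.01)
})

test_that("the exercise effect follows each group's bout schedule", {
  eff <- effectSpec(exerciseEffect = list(
    list(band = "beta2", channels = "all", factor = 2)),
    subjectSd = 0, blockSd = 0,
    blinksPerMin = 0, saccadesPerMin = 0, jumpsPerBlock = 0)
  cc <- quickConfig(blockSec = 8, effect = eff, lags = c("pre", "post1h", "post24h"))
  beta2 <- function(lag, group, i) {
    blk <- generateBlock(cc, "S01", lag, "eo_sit", 1, group,
                         seed = deriveSeed(7, i))
    welchBandPower(blk$recording)$power["Cz", "beta2"]
  }
  m <- function(lag, group) mean(sapply(1:25, beta2, lag = lag, group = group))
  # kicking group exercised before pre: pre vs post1h cancels
  expect_equal(m("pre", "kicking") / m("post1h", "kicking"), 1, tolerance = 0.1)
  # non-kicking group only exercised before post1h
  expect_equal(m("post1h", "non_kicking") / m("pre", "non_kicking"), 2,
               tolerance = 0.2)
  # nobody is exercised at 24 h
  expect_equal(m("post24h", "kicking") / m("pre", "non_kicking"), 1,
               tolerance = 0.1)
})

test_that("effect specifications are validated", {
  expect_error(effectSpec(lagEffects = list(post24h = list(
    list(band = "alpha", channels = "all", factor = 0)))), "factors must be > 0")
  expect_error(effectSpec(lagEffects = list(nextweek = list(
    list(band = "alpha", channels = "all", factor = 2)))), "unknown lag")
  expect_error(cohortConfig(nSubjects = 1))
})
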