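test_that("label shuffling conserves counts and touches nothing else", {
  ft <- makeToyFeatureTable(nSubjects = 6, seed = 9)
  sft <- shuffleLabels(ft, seed = 1)
  cd0 <- SummarizedExperiment::colData(ft)
  cd1 <- SummarizedExperiment::colData(sft)
  expect_equal(table(cd1$label), table(cd0$label))
  expect_identical(cd1$subject, cd0$subject)
  expect_identical(SummarizedExperiment::assay(sft), SummarizedExperiment::assay(ft))
  # a 2-row table is either kept or swapped, both arising over seeds
  ft2 <- makeToyFeatureTable(nSubjects = 1)
  outcomes <- vapply(1:40, function(s) {
    paste(SummarizedExperiment::colData(shuffleLabels(ft2, s))$label,
          collapse = ",")
  }, "")
  expect_length(unique(outcomes), 2)
  # within-subject mode keeps each subject's pair intact
  sw <- shuffleLabels(ft, seed = 3, mode = "within_subject")
  cdw <- SummarizedExperiment::colData(sw)
  perSubj <- tapply(cdw$label, cdw$subject, function(l) sort(l))
  expect_true(all(vapply(perSubj, function(l)
    identical(l, c("baseline", "post_impact")), TRUE)))
})

test_that("shuffled labels decorrelate from a label-aligned feature", {
  ft <- makeToyFeatureTable(nSubjects = 10, effectSize = 100, nEffect = 1,
                            seed = 10)
  feat <- SummarizedExperiment::assay(ft)[1, ]
  cors <- vapply(1:400, function(s) {
    lab <- SummarizedExperiment::colData(shuffleLabels(ft, s))$label
    cor(feat, as.integer(lab == "post_impact"))
  }, 0)
  expect_lt(abs(mean(cors)), 0.05)
})

test_that("the Welch comparison matches the closed form and handles degeneracy", {
  x <- c(0.62, 0.55, 0.71, 0.66)
  y <- c(0.50, 0.48, 0.52)
  wt <- welchTest(x, y)
  sx <- var(x) / 4; sy <- var(y) / 3
  tExp <- (mean(x) - mean(y)) / sqrt(sx + sy)
  dfExp <- (sx + sy)^2 / (sx^2 / 3 + sy^2 / 2)
  expect_equal(wt$statistic, tExp, tolerance = 1e-12)
  expect_equal(wt$df, dfExp, tolerance = 1e-12)
  expect_equal(wt$p.value, 2 * stats::pt(-abs(tExp), dfExp), tolerance = 1e-12)
  # identical constant samples: no difference, p = 1
  same <- welchTest(rep(0.5, 5), rep(0.5, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # zero spread but different means: undefined, flagged
  diff <- welchTest(rep(0.6, 5), rep(0.4, 5))
  expect_true(is.na(diff$statistic))
  expect_match(diff$note, "undefined")
})

test_that("randomization separates a strong effect from its shuffled null", {
  ft <- makeToyFeatureTable(nSubjects = 8, nFeatures = 24, effectSize = 4,
                            nEffect = 4, seed = 12)
  rt <- randomizationTest(ft, nSeeds = 4, nTrials = 3, seed = 2)
  expect_length(trueScores(rt), 4)
  expect_length(shuffledScores(rt), 4)
  expect_gt(mean(trueScores(rt)), mean(shuffledScores(rt)))
  expect_lt(pValue(rt), 0.05)
  expect_true(rt@config$shuffledSeedsFresh)
  expect_error(randomizationTest(ft, nSeeds = 1), "nSeeds")
})

test_that("subgroup restriction filters subjects; 'all' reproduces the full test", {
  ft <- makeToyFeatureTable(nSubjects = 12, effectSize = 3, seed = 13)
  full <- randomizationTest(ft, nSeeds = 3, nTrials = 2, seed = 6)
  viaAll <- subgroupTest(ft, "all", nSeeds = 3, nTrials = 2, seed = 6)
  expect_identical(trueScores(full), trueScores(viaAll))
  expect_identical(shuffledScores(full), shuffledScores(viaAll))
  gk <- subgroupTest(ft, "kicking", nSeeds = 2, nTrials = 2, seed = 6)
  expect_s4_class(gk, "RandomizationResult")
  small <- makeToyFeatureTable(nSubjects = 6)
  expect_error(subgroupTest(small, "kicking", nSeeds = 2, nTrials = 2),
               "at least k")
})

test_that("cross-lag transfer guards leakage and respects symmetry", {
  # identical feature distributions at both lags: same- and cross-lag
  # sensitivities agree within Monte-Carlo error
  ft1 <- makeToyFeatureTable(nSubjects = 10, effectSize = 3, seed = 14)
  ft24 <- ft1
  SummarizedExperiment::colData(ft24)$lag <-
    ifelse(SummarizedExperiment::colData(ft24)$lag == "pre", "pre", "post1h")
  tr <- crossLagTransfer(ft1, ft24, nSeeds = 4, nTrials = 2, seed = 3)
  expect_named(tr, c("post1h", "post24h"))
  for (lg in names(tr)) {
    expect_true(all(tr[[lg]]@sameLag >= 0 & tr[[lg]]@sameLag <= 1))
    expect_equal(mean(tr[[lg]]@sameLag), mean(tr[[lg]]@crossLag),
                 tolerance = 0.2)
  }
  # disjoint subject sets are intersected with a warning
  ft24b <- makeToyFeatureTable(nSubjects = 12, effectSize = 3, seed = 14)
  expect_warning(crossLagTransfer(ft1, ft24b, nSeeds = 2, nTrials = 2, seed = 3),
                 "intersecting")
})
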