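test_that("balanced accuracy follows its definition", {
  expect_equal(balancedAccuracy(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(balancedAccuracy(c(1, 1, 0, 0, 0), c(1, 1, 1, 1, 1)), 0.5)
  # TP=3 FN=1 TN=2 FP=2 -> (0.75 + 0.5)/2
  truth <- c(rep(1, 4), rep(0, 4))
  pred <- c(1, 1, 1, 0, 1, 1, 0, 0)
  expect_equal(balancedAccuracy(truth, pred), 0.625)
  expect_error(balancedAccuracy(rep(1, 4), rep(1, 4)), "sensitivityScore")
  expect_equal(balancedAccuracy(c("baseline", "post_impact"),
                                c("baseline", "post_impact")), 1)
})

test_that("sensitivity is the true-positive rate", {
  expect_equal(sensitivityScore(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(sensitivityScore(c(rep(1, 8), 0), c(rep(c(1, 0), 4), 0)), 0.5)
  expect_equal(sensitivityScore(c(1, 1, 1, 1, 1, 1, 1, 1),
                                c(1, 1, 0, 0, 0, 0, 0, 0)), 0.25)
  expect_error(sensitivityScore(c(0, 0), c(0, 0)), "positive")
})

test_that("F-score selection ranks discriminative features first", {
  set.seed(3)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(
    A = rnorm(n, mean = 10 * y, sd = 1),   # strongly separated
    B = rnorm(n),                          # identical distributions
    C = rep(1, n)                          # constant
  )
  expect_equal(fscoreSelect(X, y, 1), 1L)
  # constant feature never outranks a varying one
  expect_equal(sort(fscoreSelect(X, y, 2)), c(1L, 2L))
  expect_equal(fscoreSelect(X, y, 3), c(1L, 2L, 3L))
  expect_warning(sel <- fscoreSelect(X, y, 10), "clamped")
  expect_length(sel, 3)
  # F statistic matches the aov oracle
  f <- impactEEG:::fScores(X[, 1:2, drop = FALSE], y)
  want <- vapply(1:2, function(j) {
    unname(summary(stats::aov(X[, j] ~ factor(y)))[[1]]$`F value`[1])
  }, 0)
  expect_equal(unname(f), want, tolerance = 1e-10)
})

test_that("grouped CV keeps subjects intact and is seed-reproducible", {
  ft <- makeToyFeatureTable(nSubjects = 10, effectSize = 1, seed = 2)
  hp <- toyHyperParams()
  cv1 <- groupedCV(ft, hp, seed = 9)
  cv2 <- groupedCV(ft, hp, seed = 9)
  expect_identical(foldScores(cv1), foldScores(cv2))
  expect_identical(cvPredictions(cv1), cvPredictions(cv2))
  # folds partition subjects
  subj <- unlist(cv1@foldSubjects)
  expect_setequal(subj, unique(SummarizedExperiment::colData(ft)$subject))
  expect_equal(anyDuplicated(subj), 0L)
  # both rows of a subject land in the same fold
  pr <- cvPredictions(cv1)
  pr <- pr[pr$fold != "transfer", ]
  expect_true(all(tapply(pr$fold, pr$subject, function(f) length(unique(f))) == 1))
  expect_error(groupedCV(makeToyFeatureTable(nSubjects = 4), hp, seed = 1),
               "at least k")
})

test_that("a hugely separable table is classified almost perfectly", {
  ft <- makeToyFeatureTable(nSubjects = 10, effectSize = 100, seed = 4,
                            exact = TRUE)
  cv <- groupedCV(ft, toyHyperParams(), seed = 1)
  expect_gte(mean(foldScores(cv)), 0.95)
  # with continuous within-class noise the boundary error is bounded by the
  # held-out positives that undershoot the training minimum
  ftn <- makeToyFeatureTable(nSubjects = 10, effectSize = 100, seed = 4)
  cvn <- groupedCV(ftn, toyHyperParams(), seed = 1)
  expect_gte(mean(foldScores(cvn)), 0.85)
})

test_that("feature selection and training never see held-out rows", {
  ft <- makeToyFeatureTable(nSubjects = 10, effectSize = 2, seed = 5)
  hp <- toyHyperParams()
  cv <- groupedCV(ft, hp, seed = 3, returnModels = TRUE)
  cd <- SummarizedExperiment::colData(ft)
  for (fi in seq_along(cv@foldSubjects)) {
    # poison this fold's held-out values; its training artifacts must not move
    pm <- ft
    cols <- cd$subject %in% cv@foldSubjects[[fi]]
    SummarizedExperiment::assay(pm, "bandpower")[, cols] <-
      1e6 + seq_len(sum(cols) * nrow(ft))
    cvP <- groupedCV(pm, hp, seed = 3, returnModels = TRUE)
    expect_identical(cvP@selectedFeatures[[fi]], cv@selectedFeatures[[fi]])
    expect_identical(cvP@models[[fi]], cv@models[[fi]])
  }
})

test_that("hyperparameters outside the searched ranges are rejected", {
  ft <- makeToyFeatureTable(nSubjects = 6)
  hp <- toyHyperParams()
  hp$max_depth <- 12L
  expect_error(groupedCV(ft, hp, seed = 1), "outside")
  sp <- hyperParamSpace(768)
  expect_equal(sp$n_selected_features$hi, 768)
  expect_equal(sp$max_depth$lo, 2)
  expect_error(hyperParamSpace(5))
})
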