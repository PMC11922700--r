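#' Shuffle the class labels of a feature table
#'
#' Permutes the binary labels uniformly at random over all rows (default) or
#' by swapping within subjects, leaving features and subject grouping
#' untouched. Label counts are conserved under both modes.
#'
#' @param ft a [FeatureTable-class].
#' @param seed permutation seed.
#' @param mode `"rows"` (uniform permutation over all observations) or
#'   `"within_subject"` (each subject's pre/post labels swapped with
#'   probability 1/2), the latter for sensitivity analyses.
#' @return The [FeatureTable-class] with permuted labels.
#' @export
shuffleLabels <- function(ft, seed, mode = c("rows", "within_subject")) {
  mode <- match.arg(mode)
  cd <- SummarizedExperiment::colData(ft)
  labels <- cd$label
  newLabels <- withSeed(deriveSeed(seed, 77), {
    if (mode == "rows") {
      sample(labels)
    } else {
      out <- labels
      for (s in unique(cd$subject)) {
        idx <- which(cd$subject == s)
        if (stats::runif(1) < 0.5) out[idx] <- rev(out[idx])
      }
      out
    }
  })
  SummarizedExperiment::colData(ft)$label <- newLabels
  ft
}

#' Shuffled-label randomization test of classifier performance
#'
#' Model selection optimises over many models and is therefore optimistically
#' biased; this test calibrates that bias empirically. The full model-selection
#' process ([modelSearch()]) is repeated `nSeeds` times with the true labels
#' and `nSeeds` times with labels freshly re-shuffled before each search, and
#' the two distributions of best mean balanced accuracy are compared with a
#' two-tailed Welch t-test.
#'
#' @param ft a [FeatureTable-class].
#' @param nSeeds searches per condition (default 100).
#' @param nTrials trials per search (default 64).
#' @param seed master seed; true-label and shuffled-label searches draw
#'   disjoint sub-seeds from it.
#' @param strategy,k passed to [modelSearch()].
#' @param shuffleMode passed to [shuffleLabels()].
#' @return A [RandomizationResult-class].
#' @export
randomizationTest <- function(ft, nSeeds = 100, nTrials = 64, seed = 1,
                              strategy = "tpe", k = 5, shuffleMode = "rows") {
  if (nSeeds < 2) stop("nSeeds must be >= 2")
  trueScores <- vapply(seq_len(nSeeds), function(i) {
    bestScore(modelSearch(ft, seed = deriveSeed(seed, 2000, i),
                          nTrials = nTrials, strategy = strategy, k = k))
  }, 0)
  shuffledScores <- vapply(seq_len(nSeeds), function(i) {
    sft <- shuffleLabels(ft, seed = deriveSeed(seed, 3000, i), mode = shuffleMode)
    bestScore(modelSearch(sft, seed = deriveSeed(seed, 4000, i),
                          nTrials = nTrials, strategy = strategy, k = k))
  }, 0)
  wt <- welchTest(trueScores, shuffledScores)
  if (nzchar(wt$note)) warning("Welch comparison degenerate: ", wt$note)
  methods::new("RandomizationResult",
               trueScores = trueScores, shuffledScores = shuffledScores,
               statistic = wt$statistic,
               df = if (is.na(wt$df)) NA_real_ else wt$df,
               pValue = wt$p.value,
               config = list(nSeeds = nSeeds, nTrials = nTrials, seed = seed,
                             strategy = strategy, k = k,
                             shuffleMode = shuffleMode,
                             fixed = fixedModelSettings(),
                             shuffledSeedsFresh = TRUE))
}

#' Randomization test within one subject group
#'
#' Restricts the feature table to the kicking or non-kicking subjects and runs
#' [randomizationTest()] with identical seed derivation, so
#' `subgroupTest(ft, "all", ...)` reproduces `randomizationTest(ft, ...)`
#' exactly.
#'
#' @param ft a [FeatureTable-class] with a `group` column.
#' @param group `"kicking"`, `"non_kicking"` or `"all"`.
#' @param nSeeds,nTrials,seed,strategy,k see [randomizationTest()].
#' @return A [RandomizationResult-class].
#' @export
subgroupTest <- function(ft, group = c("all", "kicking", "non_kicking"),
                         nSeeds = 100, nTrials = 64, seed = 1,
                         strategy = "tpe", k = 5) {
  group <- match.arg(group)
  if (group != "all") {
    keep <- SummarizedExperiment::colData(ft)$group == group
    nSubj <- length(unique(SummarizedExperiment::colData(ft)$subject[keep]))
    if (nSubj < k) {
      stop("group '", group, "' has ", nSubj,
           " subjects; grouped CV needs at least k = ", k)
    }
    ft <- ft[, keep]
    ft <- methods::new("FeatureTable", ft)
  }
  randomizationTest(ft, nSeeds = nSeeds, nTrials = nTrials, seed = seed,
                    strategy = strategy, k = k)
}

# per-seed same-lag / cross-lag sensitivities for one training table
transferSeed <- function(ftTrain, ftOther, seed, nTrials, strategy, k) {
  sr <- modelSearch(ftTrain, seed = seed, nTrials = nTrials,
                    strategy = strategy, k = k)
  cv <- groupedCV(ftTrain, bestParams(sr), seed = seed, k = k,
                  transfer = ftOther)
  pr <- cvPredictions(cv)
  same <- pr[pr$fold != "transfer" & pr$truth == 1L, ]
  cross <- pr[pr$fold == "transfer", ]
  c(same = sensitivityScore(same$truth, same$pred),
    cross = sensitivityScore(cross$truth, cross$pred))
}

#' Cross-lag transfer of classifier sensitivity
#'
#' Tests whether the post-impact EEG signature at one recording lag carries
#' over to the other: for each training lag, seeded model searches are run on
#' that lag's table, the winning model of each search is refit under grouped
#' CV, and each fold's model predicts (a) its held-out post-impact rows at the
#' trained lag and (b) the other lag's post-impact rows restricted to the same
#' held-out subjects (the leakage guard: a subject never influences a model
#' that scores it). Because only post-impact rows are scored at the other lag,
#' performance is reported as sensitivity. Shuffled-label baselines are
#' computed identically after permuting the training labels.
#'
#' @param ft1h,ft24h [FeatureTable-class] objects for the pre-vs-1h and
#'   pre-vs-24h contrasts, sharing subjects and features.
#' @param nSeeds searches per condition (default 100).
#' @param nTrials,strategy,k see [modelSearch()].
#' @param seed master seed.
#' @return Named list of two [TransferResult-class] objects
#'   (`post1h`, `post24h`), each with Welch comparisons: same vs cross lag,
#'   same vs its shuffled baseline, cross vs its shuffled baseline.
#' @export
crossLagTransfer <- function(ft1h, ft24h, nSeeds = 100, nTrials = 64, seed = 1,
                             strategy = "tpe", k = 5) {
  s1 <- unique(SummarizedExperiment::colData(ft1h)$subject)
  s2 <- unique(SummarizedExperiment::colData(ft24h)$subject)
  common <- intersect(s1, s2)
  if (!setequal(s1, s2)) {
    warning("subject sets differ; intersecting to ", length(common), " subjects")
    ft1h <- methods::new("FeatureTable",
                         ft1h[, SummarizedExperiment::colData(ft1h)$subject %in% common])
    ft24h <- methods::new("FeatureTable",
                          ft24h[, SummarizedExperiment::colData(ft24h)$subject %in% common])
  }
  tables <- list(post1h = ft1h, post24h = ft24h)
  out <- list()
  for (li in 1:2) {
    trainLag <- names(tables)[li]
    ftTrain <- tables[[li]]
    ftOther <- tables[[3 - li]]
    res <- vapply(seq_len(nSeeds), function(i) {
      transferSeed(ftTrain, ftOther, deriveSeed(seed, 7000 + li, i),
                   nTrials, strategy, k)
    }, c(same = 0, cross = 0))
    shuf <- vapply(seq_len(nSeeds), function(i) {
      sft <- shuffleLabels(ftTrain, seed = deriveSeed(seed, 8000 + li, i))
      transferSeed(sft, ftOther, deriveSeed(seed, 9000 + li, i),
                   nTrials, strategy, k)
    }, c(same = 0, cross = 0))
    cmp <- function(a, b, what) {
      wt <- welchTest(a, b)
      data.frame(comparison = what, t = wt$statistic, df = wt$df,
                 p = wt$p.value, mean.x = wt$mean.x, mean.y = wt$mean.y,
                 stringsAsFactors = FALSE)
    }
    comparisons <- rbind(
      cmp(res["same", ], res["cross", ], "same_vs_cross"),
      cmp(res["same", ], shuf["same", ], "same_vs_shuffled"),
      cmp(res["cross", ], shuf["cross", ], "cross_vs_shuffled"))
    out[[trainLag]] <- methods::new("TransferResult",
      trainLag = trainLag, sameLag = res["same", ], crossLag = res["cross", ],
      sameLagShuffled = shuf["same", ], crossLagShuffled = shuf["cross", ],
      comparisons = comparisons)
  }
  out
}
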