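# Tree-Parzen hyperparameter proposal.
#
# Observed trials are split into "good" (top gamma fraction by score) and
# "bad"; for every parameter, a Parzen mixture (truncated Gaussians on the
# unit-transformed scale plus one uniform prior component) is fitted to each
# side, `nCandidates` draws are taken from the good-side density l(u), and the
# draw maximising l(u)/g(u) is kept. Parameters are proposed independently,
# integers by rounding on the native scale.
tpePropose <- function(space, history, gamma = 0.25, nCandidates = 24) {
  scores <- history$score
  nGood <- max(1L, ceiling(gamma * length(scores)))
  ord <- order(-scores)
  goodIdx <- ord[seq_len(nGood)]
  badIdx <- ord[-seq_len(nGood)]
  if (!length(badIdx)) badIdx <- goodIdx
  hp <- list()
  for (nm in names(space)) {
    spec <- space[[nm]]
    uAll <- vapply(history$params, function(p) paramToUnit(spec, p[[nm]]), 0)
    uGood <- uAll[goodIdx]
    uBad <- uAll[badIdx]
    bw <- function(u) max(0.08, if (length(u) > 1) stats::sd(u) else 0.25)
    dParzen <- function(x, centers, h) {
      # mixture of truncated normals on [0,1] plus a uniform prior component
      comp <- vapply(centers, function(c0) {
        stats::dnorm(x, c0, h) /
          (stats::pnorm(1, c0, h) - stats::pnorm(0, c0, h))
      }, numeric(length(x)))
      comp <- matrix(comp, nrow = length(x))
      (rowSums(comp) + 1) / (length(centers) + 1)
    }
    hG <- bw(uGood)
    hB <- bw(uBad)
    pick <- sample(c(0, seq_along(uGood)), nCandidates, replace = TRUE)
    cand <- ifelse(pick == 0, stats::runif(nCandidates),
                   stats::rnorm(nCandidates, uGood[pmax(pick, 1)], hG))
    cand <- pmin(pmax(cand, 0), 1)
    ratio <- dParzen(cand, uGood, hG) / dParzen(cand, uBad, hB)
    hp[[nm]] <- paramFromUnit(spec, cand[which.max(ratio)])
  }
  hp
}

#' Seeded hyperparameter search over grouped cross-validation
#'
#' Runs `nTrials` sequential trials, each scoring a hyperparameter draw by the
#' mean balanced accuracy of [groupedCV()], and returns the arg-max trial. The
#' default strategy is a Tree-Parzen estimator (startup trials drawn from the
#' prior, then Parzen-density proposals); `"random"` draws every trial from
#' the prior with identical distributions. Trial i derives its own seed from
#' `(seed, i)`, so trials are independent of execution order and the whole
#' search is reproducible from `seed`.
#'
#' @param ft a [FeatureTable-class].
#' @param seed search seed (controls the sampler and all CV/model seeds).
#' @param nTrials search budget (default 64).
#' @param strategy `"tpe"` (default) or `"random"`.
#' @param k CV folds.
#' @param nStartup prior-only trials before Parzen proposals begin.
#' @return A [SearchResult-class].
#' @export
modelSearch <- function(ft, seed = 1, nTrials = 64, strategy = c("tpe", "random"),
                        k = 5, nStartup = max(4L, nTrials %/% 4L)) {
  strategy <- match.arg(strategy)
  if (nTrials < 1) stop("nTrials must be >= 1")
  nFeat <- nrow(ft)
  space <- hyperParamSpace(nFeat)
  history <- list(params = list(), score = numeric())
  for (i in seq_len(nTrials)) {
    trialSeed <- deriveSeed(seed, 1000, i)
    hp <- withSeed(trialSeed, {
      if (strategy == "random" || i <= nStartup) {
        sampleHyperParams(space)
      } else {
        tpePropose(space, history)
      }
    })
    cv <- groupedCV(ft, hp, seed = trialSeed, k = k)
    history$params[[i]] <- hp
    history$score[i] <- mean(foldScores(cv))
  }
  best <- which.max(history$score)
  trials <- cbind(
    trial = seq_len(nTrials),
    do.call(rbind, lapply(history$params, function(p) as.data.frame(p))),
    score = history$score)
  methods::new("SearchResult",
               bestParams = history$params[[best]],
               bestScore = history$score[best],
               trials = trials, seed = as.integer(seed %% 2147483647),
               strategy = strategy)
}
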