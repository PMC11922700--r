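#' @importFrom xgboost xgb.train xgb.DMatrix xgb.save.raw
NULL

# fixed model settings, recorded in every result's provenance
fixedModelSettings <- function() {
  list(nrounds = 100, booster = "gbtree", objective = "binary:logistic",
       eval_metric = "logloss", gamma = 1, tree_method = "hist")
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity. Robust to class imbalance; 0.5 for
#' any constant prediction on mixed labels.
#'
#' @param truth,pred vectors coercible to the binary labels; the positive
#'   class is `"post_impact"` (or 1/TRUE).
#' @return Scalar in \[0, 1\].
#' @export
balancedAccuracy <- function(truth, pred) {
  y <- asBinary(truth)
  p <- asBinary(pred)
  if (length(unique(y)) < 2) {
    stop("both classes must be present in the labels; for positive-only ",
         "evaluation use sensitivityScore()")
  }
  sens <- mean(p[y == 1] == 1)
  spec <- mean(p[y == 0] == 0)
  (sens + spec) / 2
}

#' Sensitivity (true-positive rate)
#'
#' @param truth,pred as in [balancedAccuracy()]; at least one positive label
#'   required.
#' @return TP / (TP + FN).
#' @export
sensitivityScore <- function(truth, pred) {
  y <- asBinary(truth)
  p <- asBinary(pred)
  if (!any(y == 1)) stop("sensitivity undefined without positive labels")
  mean(p[y == 1] == 1)
}

# fold scorer: balanced accuracy when both classes are present; with a
# single-class held-out fold (possible under shuffled labels) the macro recall
# reduces to the recall of the present class
foldScoreFn <- function(truth, pred) {
  y <- asBinary(truth)
  if (length(unique(y)) == 2) balancedAccuracy(truth, pred)
  else mean(asBinary(pred) == y)
}

asBinary <- function(x) {
  if (is.character(x) || is.factor(x)) {
    as.integer(as.character(x) == "post_impact")
  } else {
    as.integer(x > 0.5)
  }
}

#' Rank features by one-way ANOVA F-score and keep the top k
#'
#' Computes, on training data only, the two-class one-way ANOVA F statistic of
#' every feature and returns the indices of the `k` largest, ties broken by
#' feature index. Zero-variance features get F = 0.
#'
#' @param X observations x features numeric matrix (training rows only).
#' @param y binary labels aligned to rows.
#' @param k number of features to keep; clamped to `ncol(X)` with a warning.
#' @return Integer vector of `k` feature column indices, descending by F.
#' @export
fscoreSelect <- function(X, y, k) {
  y <- asBinary(y)
  stopifnot(length(unique(y)) == 2)
  if (k > ncol(X)) {
    warning("k exceeds the number of features; clamped")
    k <- ncol(X)
  }
  f <- fScores(X, y)
  order(-f, seq_along(f))[seq_len(k)]
}

# vectorised two-class one-way ANOVA F statistics
fScores <- function(X, y) {
  n <- nrow(X)
  n1 <- sum(y == 1)
  n0 <- n - n1
  m <- colMeans(X)
  m1 <- colMeans(X[y == 1, , drop = FALSE])
  m0 <- colMeans(X[y == 0, , drop = FALSE])
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ssw <- colSums((X[y == 1, , drop = FALSE] - rep(m1, each = n1))^2) +
    colSums((X[y == 0, , drop = FALSE] - rep(m0, each = n0))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[ssb == 0] <- 0          # constant or identically-distributed-mean feature
  f[ssw == 0 & ssb > 0] <- Inf
  f
}

#' The searched hyperparameter space
#'
#' Distributions for the model search: maximum tree depth (uniform integers
#' 2..8), alpha regularisation (log-uniform 1e-15..1), lambda regularisation
#' (log-uniform 1e-15..100), row subsampling per tree (uniform 0.1..1),
#' column subsampling per tree (uniform 0.2..1), learning rate (log-uniform
#' 0.01..1) and the number of F-score-selected features (uniform integers 10..
#' `nFeatures`, resolved from the table at search start).
#'
#' @param nFeatures width of the feature table.
#' @return Named list of parameter specifications.
#' @export
hyperParamSpace <- function(nFeatures) {
  stopifnot(nFeatures >= 10)
  list(
    max_depth = list(type = "int", lo = 2, hi = 8),
    reg_alpha = list(type = "log", lo = 1e-15, hi = 1),
    reg_lambda = list(type = "log", lo = 1e-15, hi = 100),
    subsample = list(type = "unif", lo = 0.1, hi = 1.0),
    colsample_bytree = list(type = "unif", lo = 0.2, hi = 1.0),
    eta = list(type = "log", lo = 0.01, hi = 1.0),
    n_selected_features = list(type = "int", lo = 10, hi = nFeatures)
  )
}

# unit-scale <-> native-scale transforms for one parameter spec
paramFromUnit <- function(spec, u) {
  v <- switch(spec$type,
              int = spec$lo + u * (spec$hi - spec$lo),
              unif = spec$lo + u * (spec$hi - spec$lo),
              log = exp(log(spec$lo) + u * (log(spec$hi) - log(spec$lo))))
  if (spec$type == "int") v <- as.integer(round(v))
  min(max(v, spec$lo), spec$hi)
}

paramToUnit <- function(spec, v) {
  u <- switch(spec$type,
              int = (v - spec$lo) / (spec$hi - spec$lo),
              unif = (v - spec$lo) / (spec$hi - spec$lo),
              log = (log(v) - log(spec$lo)) / (log(spec$hi) - log(spec$lo)))
  min(max(u, 0), 1)
}

sampleHyperParams <- function(space) {
  hp <- lapply(space, function(spec) paramFromUnit(spec, stats::runif(1)))
  hp
}

validateHyperParams <- function(hp, space) {
  for (nm in names(space)) {
    spec <- space[[nm]]
    v <- hp[[nm]]
    if (is.null(v) || v < spec$lo || v > spec$hi) {
      stop("hyperparameter ", nm, " missing or outside [", spec$lo, ", ",
           spec$hi, "]")
    }
  }
  invisible(TRUE)
}

# train one boosted-tree model on selected columns; returns the fitted model
fitBoostedTrees <- function(Xtr, ytr, hp, seed) {
  fx <- fixedModelSettings()
  params <- list(objective = fx$objective, eval_metric = fx$eval_metric,
                 booster = fx$booster, tree_method = fx$tree_method,
                 gamma = fx$gamma, nthread = 1,
                 max_depth = hp$max_depth, eta = hp$eta,
                 alpha = hp$reg_alpha, lambda = hp$reg_lambda,
                 subsample = hp$subsample,
                 colsample_bytree = hp$colsample_bytree,
                 seed = as.integer(seed %% 2147483647))
  dtr <- xgboost::xgb.DMatrix(Xtr, label = ytr, nthread = 1)
  xgboost::xgb.train(params = params, data = dtr, nrounds = fx$nrounds,
                     verbose = 0)
}

# deterministic subject fold assignment: shuffle by seed, deal round-robin
subjectFolds <- function(subjects, k, seed) {
  subj <- sort(unique(subjects))
  if (length(subj) < k) {
    stop("need at least k = ", k, " subjects for grouped CV, got ", length(subj))
  }
  shuffled <- withSeed(deriveSeed(seed, 11), sample(subj))
  split(shuffled, rep_len(seq_len(k), length(shuffled)))
}

#' Subject-grouped k-fold cross-validation
#'
#' Partitions subjects (not rows) into `k` folds, so both of a subject's
#' observations always share a fold and scores estimate performance on new
#' participants. Within each fold, F-score feature selection and model fitting
#' see training rows only; the held-out fold is scored by balanced accuracy.
#' Fully reproducible from `seed`.
#'
#' @param ft a [FeatureTable-class].
#' @param hp hyperparameter list (see [hyperParamSpace()] for fields).
#' @param seed integer seed controlling fold assignment and model fitting.
#' @param k number of folds (default 5).
#' @param transfer optional second [FeatureTable-class] sharing subjects and
#'   features; each fold's model additionally predicts the transfer table's
#'   post-impact rows restricted to that fold's held-out subjects.
#' @param returnModels keep each fold's serialised model in the result
#'   (default off; used e.g. to audit that held-out data never influence
#'   training).
#' @return A [CVResult-class]; when `transfer` is given, its `predictions`
#'   data.frame also contains rows with `fold` tagged `"transfer"`.
#' @export
groupedCV <- function(ft, hp, seed, k = 5, transfer = NULL,
                      returnModels = FALSE) {
  cd <- SummarizedExperiment::colData(ft)
  X <- t(SummarizedExperiment::assay(ft, "bandpower"))
  y <- asBinary(cd$label)
  validateHyperParams(hp, hyperParamSpace(ncol(X)))
  folds <- subjectFolds(cd$subject, k, seed)
  if (!is.null(transfer)) {
    tcd <- SummarizedExperiment::colData(transfer)
    tX <- t(SummarizedExperiment::assay(transfer, "bandpower"))
    tPost <- which(tcd$label == "post_impact")
  }
  foldScores <- numeric(k)
  foldSubjects <- vector("list", k)
  selected <- vector("list", k)
  models <- list()
  predList <- list()
  for (fi in seq_len(k)) {
    testSubj <- folds[[fi]]
    isTest <- cd$subject %in% testSubj
    sel <- fscoreSelect(X[!isTest, , drop = FALSE], y[!isTest],
                        hp$n_selected_features)
    model <- fitBoostedTrees(X[!isTest, sel, drop = FALSE], y[!isTest], hp,
                             seed = deriveSeed(seed, 500, fi))
    prob <- predict(model, xgboost::xgb.DMatrix(X[isTest, sel, drop = FALSE],
                                                nthread = 1))
    pred <- as.integer(prob > 0.5)
    foldScores[fi] <- foldScoreFn(y[isTest], pred)
    foldSubjects[[fi]] <- testSubj
    selected[[fi]] <- sel
    if (returnModels) models[[fi]] <- xgboost::xgb.save.raw(model)
    predList[[length(predList) + 1L]] <- data.frame(
      subject = cd$subject[isTest], lag = cd$lag[isTest],
      truth = y[isTest], pred = pred, fold = as.character(fi),
      stringsAsFactors = FALSE)
    if (!is.null(transfer)) {
      tidx <- tPost[tcd$subject[tPost] %in% testSubj]
      if (length(tidx)) {
        tprob <- predict(model, xgboost::xgb.DMatrix(tX[tidx, sel, drop = FALSE],
                                                     nthread = 1))
        predList[[length(predList) + 1L]] <- data.frame(
          subject = tcd$subject[tidx], lag = tcd$lag[tidx],
          truth = 1L, pred = as.integer(tprob > 0.5), fold = "transfer",
          stringsAsFactors = FALSE)
      }
    }
  }
  methods::new("CVResult", foldScores = foldScores, foldSubjects = foldSubjects,
               predictions = do.call(rbind, predList),
               selectedFeatures = selected, models = models,
               seed = as.integer(seed %% 2147483647))
}
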