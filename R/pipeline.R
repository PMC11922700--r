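#' Streaming cohort feature extraction
#'
#' Generates a synthetic cohort block by block, optionally preprocesses each
#' block, computes its Welch band powers, and assembles session-level feature
#' vectors without ever holding more than one raw block in memory — the
#' full-scale design (36 x 3 x 8 blocks of 2.5 min) is ~17 GB as doubles, so
#' streaming is the only practical route at that scale.
#'
#' @param config a [cohortConfig()].
#' @param preprocessing `"none"` (Welch directly on the simulated signal,
#'   appropriate for artifact-free cohorts: the synthetic background is already
#'   zero-mean and band-limited), `"full"` (the entire [preprocess()] chain) or
#'   `"no_ica"` (filter + reference + jump rejection, for artifact studies that
#'   keep ocular templates out of the loop).
#' @param params,scheme Welch settings and band scheme.
#' @return List with `sessions` (list of [sessionFeatures()] results, one per
#'   subject x lag) and `manifest` (ground truth, see [generateCohort()]).
#' @export
cohortFeatureVectors <- function(config, preprocessing = c("none", "full", "no_ica"),
                                 params = welchParams(fs = config$fs),
                                 scheme = bandScheme()) {
  preprocessing <- match.arg(preprocessing)
  powers <- walkCohort(config, function(rec, art) {
    rec <- switch(preprocessing,
                  none = rec,
                  full = preprocess(rec, seed = deriveSeed(config$seed, 55,
                                                           rec@block)),
                  no_ica = preprocess(rec, runICA = FALSE))
    bp <- welchBandPower(rec, params, scheme)
    list(subject = subjectID(rec), lag = sessionLag(rec),
         group = subjectGroup(rec), condition = recordingCondition(rec),
         power = bp$power, nWindows = bp$nWindows, missing = bp$missing)
  })
  manifest <- powers$manifest
  key <- vapply(powers$recordings, function(p) paste(p$subject, p$lag), "")
  sessions <- lapply(split(powers$recordings, key), sessionFromPowers,
                     scheme = scheme, montage = config$montage)
  list(sessions = unname(sessions), manifest = manifest)
}

# assemble a sessionFeatures()-shaped record from per-block band powers
sessionFromPowers <- function(blockPowers, scheme, montage) {
  idx <- featureIndex(montage, scheme)
  values <- stats::setNames(rep(NA_real_, nrow(idx)), idx$name)
  missing <- stats::setNames(rep(TRUE, length(VALID_CONDITIONS)), VALID_CONDITIONS)
  nBlocks <- nWindows <- stats::setNames(integer(length(VALID_CONDITIONS)),
                                         VALID_CONDITIONS)
  for (cond in VALID_CONDITIONS) {
    bp <- Filter(function(p) p$condition == cond && !p$missing, blockPowers)
    if (!length(bp)) next
    avg <- Reduce(`+`, lapply(bp, `[[`, "power")) / length(bp)
    missing[cond] <- FALSE
    nBlocks[cond] <- length(bp)
    nWindows[cond] <- sum(vapply(bp, `[[`, 0L, "nWindows"))
    sel <- idx$condition == cond
    values[sel] <- avg[cbind(match(idx$channel[sel], montage$label),
                             match(idx$band[sel], names(scheme)))]
  }
  list(values = values, missing = missing, nBlocks = nBlocks,
       nWindows = nWindows, subject = blockPowers[[1]]$subject,
       lag = blockPowers[[1]]$lag, group = blockPowers[[1]]$group)
}

#' Run the full analysis pipeline from a single configuration
#'
#' simulate -> (preprocess) -> featurize -> classify -> infer, driven by one
#' configuration object (or YAML/JSON file) and one master seed that fans out
#' to every stage. Emits the three headline analyses — pre-vs-1h and
#' pre-vs-24h randomization tests and, optionally, cross-lag transfer and
#' subgroup contrasts — plus JSON results, CSV score distributions and a
#' manifest stamped with the config hash and package version.
#'
#' @param config a list (or path to a YAML/JSON file) with elements `cohort`
#'   (arguments to [cohortConfig()]; `effect` given as plain lists), `
#'   preprocessing` (`"none"`, `"full"`, `"no_ica"`), `inference` (list:
#'   `nSeeds`, `nTrials`, `strategy`, `k`, `lags`, logicals `transfer`,
#'   `subgroups`), `outDir` (optional; results written when given) and `seed`.
#' @return Invisible list with the feature tables, per-lag
#'   [RandomizationResult-class] objects, transfer and subgroup results, the
#'   manifest and the output file index.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  inf <- config$inference
  if (is.null(inf)) inf <- list()
  inf <- utils::modifyList(list(nSeeds = 100, nTrials = 64, strategy = "tpe",
                                k = 5, lags = c("post1h", "post24h"),
                                transfer = FALSE, subgroups = FALSE), inf)
  cohortArgs <- if (is.null(config$cohort)) list() else config$cohort
  if (!is.null(cohortArgs$effect) && !inherits(cohortArgs$effect, "EffectSpec")) {
    cohortArgs$effect <- do.call(effectSpec, cohortArgs$effect)
  }
  cohortArgs$seed <- deriveSeed(seed, 1)
  cc <- do.call(cohortConfig, cohortArgs)
  preprocessing <- if (is.null(config$preprocessing)) "none" else config$preprocessing
  message("stage simulate+featurize: ", cc$nSubjects, " subjects, lags ",
          paste(cc$lags, collapse = "/"), ", preprocessing=", preprocessing)
  fv <- tryCatch(cohortFeatureVectors(cc, preprocessing = preprocessing),
                 error = function(e) stop("stage simulate/featurize failed: ",
                                          conditionMessage(e)))
  tables <- list()
  results <- list()
  for (lag in inf$lags) {
    tables[[lag]] <- assembleFeatureTable(fv$sessions, c("pre", lag))
    message("stage infer (", lag, "): nSeeds=", inf$nSeeds,
            " nTrials=", inf$nTrials)
    results[[lag]] <- randomizationTest(
      tables[[lag]], nSeeds = inf$nSeeds, nTrials = inf$nTrials,
      seed = deriveSeed(seed, 2, match(lag, VALID_LAGS)),
      strategy = inf$strategy, k = inf$k)
  }
  transfer <- NULL
  if (isTRUE(inf$transfer) && all(c("post1h", "post24h") %in% names(tables))) {
    message("stage infer: cross-lag transfer")
    transfer <- crossLagTransfer(tables$post1h, tables$post24h,
                                 nSeeds = inf$nSeeds, nTrials = inf$nTrials,
                                 seed = deriveSeed(seed, 3),
                                 strategy = inf$strategy, k = inf$k)
  }
  subgroups <- NULL
  if (isTRUE(inf$subgroups)) {
    subgroups <- list()
    for (lag in inf$lags) {
      for (g in VALID_GROUPS) {
        message("stage infer: subgroup ", g, " @ ", lag)
        subgroups[[paste(g, lag, sep = ".")]] <- subgroupTest(
          tables[[lag]], group = g, nSeeds = inf$nSeeds,
          nTrials = inf$nTrials,
          seed = deriveSeed(seed, 4, match(lag, VALID_LAGS)),
          strategy = inf$strategy, k = inf$k)
      }
    }
  }
  bundle <- list(tables = tables, randomization = results,
                 transfer = transfer, subgroups = subgroups,
                 manifest = fv$manifest,
                 configHash = configHash(config),
                 version = as.character(utils::packageVersion("impactEEG")))
  if (!is.null(config$outDir)) {
    bundle$files <- writeResultBundle(bundle, config$outDir)
  }
  invisible(bundle)
}

# serialize the headline numbers + score distributions under outDir
writeResultBundle <- function(bundle, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  files <- character()
  summ <- list(configHash = bundle$configHash, version = bundle$version)
  for (lag in names(bundle$randomization)) {
    r <- bundle$randomization[[lag]]
    summ[[lag]] <- list(meanTrue = mean(trueScores(r)),
                        meanShuffled = mean(shuffledScores(r)),
                        t = welchStatistic(r), df = r@df, p = pValue(r))
    csv <- file.path(outDir, paste0("scores_", lag, ".csv"))
    utils::write.csv(data.frame(seed = seq_along(trueScores(r)),
                                true = trueScores(r),
                                shuffled = shuffledScores(r)),
                     csv, row.names = FALSE)
    files <- c(files, csv)
  }
  for (lag in names(bundle$transfer)) {
    tr <- bundle$transfer[[lag]]
    summ[[paste0("transfer_", lag)]] <- list(
      sameLag = mean(tr@sameLag), crossLag = mean(tr@crossLag),
      comparisons = tr@comparisons)
  }
  for (nm in names(bundle$subgroups)) {
    r <- bundle$subgroups[[nm]]
    summ[[paste0("subgroup_", nm)]] <- list(
      meanTrue = mean(trueScores(r)), meanShuffled = mean(shuffledScores(r)),
      t = welchStatistic(r), p = pValue(r))
  }
  js <- file.path(outDir, "results.json")
  jsonlite::write_json(summ, js, auto_unbox = TRUE, digits = NA, force = TRUE)
  files <- c(files, js)
  for (lag in names(bundle$tables)) {
    csv <- file.path(outDir, paste0("features_", lag, ".csv"))
    writeFeatureTable(bundle$tables[[lag]], csv,
                      meta = list(scaling = "density",
                                  scheme = bandScheme(),
                                  configHash = bundle$configHash,
                                  version = bundle$version))
    files <- c(files, csv)
  }
  files
}
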