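#' Derive a child seed from a parent seed and integer keys
#'
#' Counter-based seed splitting: the master seed and any number of integer keys
#' are folded through a multiplicative congruential mix modulo 2^31 - 1, so
#' every (subject, session, block, stage) gets an independent, order-free
#' sub-seed. All randomness in the package flows through this derivation.
#'
#' @param seed parent seed (integer-valued).
#' @param ... integer keys identifying the child stream.
#' @return A single integer in [1, 2^31 - 2].
#' @export
deriveSeed <- function(seed, ...) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (k in c(1, as.numeric(unlist(list(...))))) {
    s <- (s * 69069 + k * 12345 + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

#' Two-sample Welch t-test with degenerate-sample handling
#'
#' Thin wrapper around [stats::t.test()] (unequal variances, two-tailed) that
#' reports `t = 0, p = 1` when the two samples are identical constants (no
#' evidence of a difference, zero spread) and a flagged `NA` when the spread is
#' zero but the means differ (the statistic is undefined).
#'
#' @param x,y numeric score samples.
#' @return List with `statistic`, `df` (Welch-Satterthwaite), `p.value`,
#'   `mean.x`, `mean.y` and a character `note` ("" when the test was regular).
#' @export
welchTest <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  vx <- stats::var(x)
  vy <- stats::var(y)
  if ((is.na(vx) || vx == 0) && (is.na(vy) || vy == 0)) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(list(statistic = 0, df = NA_real_, p.value = 1,
                  mean.x = mean(x), mean.y = mean(y),
                  note = "zero-variance samples with equal means"))
    }
    return(list(statistic = NA_real_, df = NA_real_, p.value = NA_real_,
                mean.x = mean(x), mean.y = mean(y),
                note = "zero-variance samples with unequal means; t undefined"))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, mean.x = mean(x), mean.y = mean(y), note = "")
}

#' Polynomial hash of a serialised R object
#'
#' Used to stamp result bundles with a configuration fingerprint so a saved
#' result can be matched to the exact configuration that produced it.
#'
#' @param x any serialisable R object.
#' @return Hex string of a 31-bit polynomial hash.
#' @export
configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  m <- 2147483647
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%08x", as.integer(h))
}

# internal: run expr with a local RNG state seeded from `seed`
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
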