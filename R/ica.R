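# FastICA with symmetric decorrelation and the logcosh contrast.
#
# Input X is channels x samples. The data are row-centered and whitened via an
# eigendecomposition of the channel covariance; the unmixing matrix W is
# estimated by fixed-point iteration with symmetric orthogonalisation. Scale
# and sign of components are arbitrary; template matching downstream uses
# absolute correlations, which are invariant to both.
#
# Returns: S (nComp x samples sources), A (channels x nComp mixing matrix such
# that X ~= A %*% S + mean), mean (row means), converged flag.
fastICA <- function(X, nComp, maxIter = 200, tol = 1e-5, alpha = 1,
                    failTol = 0.05, estimateEvery = 1L) {
  nch <- nrow(X)
  ns <- ncol(X)
  stopifnot(nComp >= 1, nComp <= nch)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / ns
  eg <- eigen(C, symmetric = TRUE)
  keep <- seq_len(nComp)
  d <- eg$values[keep]
  d[d < .Machine$double.eps] <- .Machine$double.eps
  K <- diag(1 / sqrt(d), nComp) %*% t(eg$vectors[, keep, drop = FALSE]) # whitener
  Z <- K %*% Xc                                   # nComp x ns, identity cov
  # the unmixing matrix is estimated on a decimated copy (topographies and
  # higher-order statistics are stable under modest downsampling); sources are
  # then extracted from the full-rate data
  Zest <- if (estimateEvery > 1L) {
    Z[, seq(1L, ns, by = as.integer(estimateEvery)), drop = FALSE]
  } else Z
  nsE <- ncol(Zest)
  W <- matrix(stats::rnorm(nComp * nComp), nComp)
  symDecor <- function(W) {
    sv <- svd(W)
    sv$u %*% t(sv$v)
  }
  W <- symDecor(W)
  delta <- Inf
  compDelta <- rep(Inf, nComp)
  for (it in seq_len(maxIter)) {
    WX <- W %*% Zest
    G <- tanh(alpha * WX)
    gDer <- alpha * rowMeans(1 - G^2)
    W1 <- (G %*% t(Zest)) / nsE - diag(gDer, nComp) %*% W
    W1 <- symDecor(W1)
    compDelta <- abs(abs(rowSums(W1 * W)) - 1)
    delta <- max(compDelta)
    W <- W1
    if (delta < tol) break
  }
  # a near-Gaussian background subspace rotates freely under symmetric
  # orthogonalisation and may never meet a strict global fixed-point
  # criterion; strongly non-Gaussian (artifact) components stabilise early.
  # Callers can therefore judge convergence per component via compDelta.
  converged <- delta < failTol
  S <- W %*% Z
  # mixing matrix: X ~= A S; A = pinv(W K) = Kpinv W' (W orthogonal)
  Kpinv <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(d), nComp)
  A <- Kpinv %*% t(W)
  list(S = S, A = A, mean = mu, converged = converged, iterations = it,
       delta = delta, compDelta = compDelta)
}
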