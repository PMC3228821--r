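# Decomposition of the standardized expression matrix: permutation-corrected
# screeplot for the number of components, multi-restart symmetric FastICA
# (logcosh negentropy, alpha = 1), and the two component filters
# (individual-specific patterns, signature kurtosis).

# E[log cosh(Z)] for Z ~ N(0,1); reference value of the negentropy proxy.
.EG_LOGCOSH <- 0.3745672075

# Eigenvalue scree of a genes x samples matrix as fractions of total variance.
.screeFractions <- function(x) {
  d2 <- svd(x, nu = 0, nv = 0)$d^2
  d2 / sum(d2)
}

#' Choose the number of components by a permutation-corrected screeplot
#'
#' Compares the observed eigenvalue scree of the standardized matrix with a
#' null scree obtained by permuting the samples independently within each
#' gene. The null curve at step s is corrected for the signal already
#' extracted: the cumulative excess variance (observed minus null) of the
#' first s-1 components is removed from the remaining null variance, and the
#' bar for the s-th observed eigenvalue is the null's largest eigenvalue
#' rescaled to that remaining variance (the size of the top eigenvalue a
#' pure-noise residual of that magnitude would produce). The chosen K is the
#' last component before the observed curve crosses below the corrected
#' null curve.
#'
#' @param x \linkS4class{ExpressionData} in state `"standardized"`.
#' @param nPerm number of permuted matrices (default 1); more permutations
#'   average the null curves.
#' @param seed integer seed for the permutations.
#' @param nullExcess relative margin by which an observed eigenvalue must
#'   exceed the corrected null to count as signal (default 0.05); absorbs the
#'   sampling fluctuation of a single permutation curve.
#' @return integer, the selected number of components (0 for pure noise).
#' @export
chooseNumComponents <- function(x, nPerm = 1, seed = 1, nullExcess = 0.05) {
  stopIfNot(transformState(x) == "standardized",
            "component selection expects a standardized matrix")
  v <- exprValues(x)
  stopIfNot(nrow(v) >= 3 && ncol(v) >= 3,
            "need at least 3 genes and 3 samples")
  obs <- .screeFractions(v)
  set.seed(as.integer(seed))
  nullFrac <- rep(0, length(obs))
  for (p in seq_len(nPerm)) {
    vp <- t(apply(v, 1, sample))
    nullFrac <- nullFrac + .screeFractions(vp)
  }
  nullFrac <- nullFrac / nPerm
  m <- length(obs)
  excess <- 0        # cumulative observed - null of preceding components
  for (s in seq_len(m)) {
    remaining <- sum(nullFrac[s:m])
    fac <- if (remaining > 0) max(1 - excess / remaining, 0) else 0
    # After s-1 accepted components the residual behaves like a pure-noise
    # matrix holding the not-yet-explained variance, whose largest
    # eigenvalue is the null's top eigenvalue rescaled to that variance.
    corrected <- nullFrac[1] * fac
    if (obs[s] <= corrected * (1 + nullExcess) || obs[s] < 1e-12)
      return(s - 1L)
    excess <- excess + (obs[s] - nullFrac[s])
  }
  as.integer(m)
}

#' Excess kurtosis of a signature
#'
#' Moment-form kurtosis \eqn{m_4 / m_2^2 - 3} (a Gaussian scores 0); set
#' `excess = FALSE` for the raw kurtosis (Gaussian scores 3).
#'
#' @param sCol numeric vector (at least 4 values, nonzero variance).
#' @param excess return excess (default) or raw kurtosis.
#' @return numeric scalar.
#' @export
computeKurtosis <- function(sCol, excess = TRUE) {
  stopIfNot(length(sCol) >= 4, "need at least 4 values")
  x <- sCol - mean(sCol)
  m2 <- mean(x^2)
  if (m2 == 0) stop("zero variance", call. = FALSE)
  k <- mean(x^4) / m2^2
  if (excess) k - 3 else k
}

#' Flag a pattern dominated by a single individual
#'
#' An individual's share of a pattern's variability is
#' \eqn{(a_j - \bar a)^2 / \sum_{j'} (a_{j'} - \bar a)^2}; the component is
#' flagged when the maximum share strictly exceeds `threshold`.
#'
#' @param aRow numeric activations over samples (>= 3, nonzero variance).
#' @param threshold share above which the component is individual-specific
#'   (default 0.10).
#' @return list with `flag`, `maxShare` and `sample` (index of the maximal
#'   individual).
#' @export
flagIndividualSpecific <- function(aRow, threshold = 0.10) {
  stopIfNot(length(aRow) >= 3, "need at least 3 samples")
  dev2 <- (aRow - mean(aRow))^2
  tot <- sum(dev2)
  if (tot == 0) stop("zero-variance pattern", call. = FALSE)
  share <- dev2 / tot
  j <- which.max(share)
  list(flag = share[j] > threshold, maxShare = unname(share[j]),
       sample = unname(j))
}

# One symmetric FastICA run on whitened data Y (G x K, unit covariance):
# fixed-point iteration for the logcosh contrast, symmetric decorrelation.
.fastICACore <- function(Y, W, alpha, tol, maxIter) {
  G <- nrow(Y)
  sym <- function(M) {
    e <- eigen(crossprod(M), symmetric = TRUE)
    M %*% (e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)),
                              ncol(M)) %*% t(e$vectors))
  }
  W <- sym(W)
  converged <- FALSE
  iter <- 0
  while (iter < maxIter) {
    iter <- iter + 1
    U <- Y %*% W
    gU <- tanh(alpha * U)
    W1 <- crossprod(Y, gU) / G -
      sweep(W, 2, colMeans(alpha * (1 - gU^2)), `*`)
    W1 <- sym(W1)
    delta <- max(abs(1 - abs(colSums(W1 * W))))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  list(W = W, converged = converged, iter = iter)
}

#' Multi-restart symmetric FastICA decomposition X ~ S A
#'
#' Reduces the standardized matrix to its rank-K SVD subspace, extracts K
#' components by the symmetric (parallel) fixed-point iteration maximizing
#' the logcosh approximation of negentropy with `alpha = 1` (genes are the
#' observations), and among `nRestarts` seeded runs keeps the one with the
#' largest summed negentropy proxy. Components are oriented so each
#' signature's skewness is >= 0 and scaled so signature columns have unit
#' variance (the pattern matrix absorbs the magnitude). Per-component excess
#' kurtosis and the individual-specific flag are computed on the result.
#'
#' @param x \linkS4class{ExpressionData} in state `"standardized"`.
#' @param K number of components (<= min(genes, samples)).
#' @param nRestarts random restarts (default 10).
#' @param seed integer; restart r uses seed + r - 1.
#' @param alpha logcosh parameter (default 1).
#' @param tol convergence tolerance on the unmixing rotation (default 1e-4).
#' @param maxIter iteration cap per restart (default 200).
#' @param kurtosisMin threshold of the signature kurtosis filter, applied as
#'   excess kurtosis (default 3).
#' @param shareThreshold individual-specific share threshold (default 0.10).
#' @return A \linkS4class{Decomposition}.
#' @export
runICA <- function(x, K, nRestarts = 10, seed = 1, alpha = 1, tol = 1e-4,
                   maxIter = 200, kurtosisMin = 3, shareThreshold = 0.10) {
  stopIfNot(transformState(x) == "standardized",
            "ICA expects a standardized matrix")
  v <- exprValues(x)
  G <- nrow(v)
  stopIfNot(K >= 1 && K <= min(dim(v)), "invalid K")
  sv <- svd(v, nu = K, nv = K)
  Y <- sv$u * sqrt(G)
  best <- NULL
  diagnostics <- character()
  for (r in seq_len(nRestarts)) {
    set.seed(as.integer(seed) + r - 1L)
    W0 <- matrix(stats::rnorm(K * K), K, K)
    run <- .fastICACore(Y, W0, alpha, tol, maxIter)
    if (!run$converged) {
      diagnostics <- c(diagnostics,
                       sprintf("restart %d: no convergence in %d iterations",
                               r, run$iter))
      next
    }
    U <- Y %*% run$W
    neg <- (colMeans(log(cosh(alpha * U))) / alpha - .EG_LOGCOSH)^2
    if (is.null(best) || sum(neg) > sum(best$neg))
      best <- list(W = run$W, neg = neg, restart = r)
  }
  if (is.null(best))
    stop("no ICA restart converged: ",
         paste(diagnostics, collapse = "; "), call. = FALSE)

  S <- Y %*% best$W
  A <- t(best$W) %*% (diag(sv$d[seq_len(K)], K) %*% t(sv$v)) / sqrt(G)
  sdS <- sqrt(colVars(S))
  S <- sweep(S, 2, sdS, `/`)
  A <- A * sdS
  flip <- vapply(seq_len(K), function(k) momentSkewness(S[, k]) < 0,
                 logical(1))
  S[, flip] <- -S[, flip, drop = FALSE]
  A[flip, ] <- -A[flip, , drop = FALSE]
  ids <- paste0("IC", seq_len(K))
  dimnames(S) <- list(rownames(v), ids)
  dimnames(A) <- list(ids, colnames(v))
  kur <- apply(S, 2, computeKurtosis)
  indiv <- vapply(seq_len(K), function(k)
    flagIndividualSpecific(A[k, ], shareThreshold)$flag, logical(1))
  new("Decomposition", S = S, A = A, componentIds = ids,
      kurtosis = unname(kur), individualSpecific = indiv,
      kurtosisPass = unname(kur) >= kurtosisMin,
      negentropy = unname(best$neg))
}

#' Retain informative components
#'
#' Drops individual-specific components first, then components whose
#' signature excess kurtosis falls below `kurtosisMin`; the order of the
#' survivors is preserved.
#'
#' @param d a \linkS4class{Decomposition} with flags computed.
#' @param kurtosisMin kurtosis threshold (default 3, on the excess scale).
#' @return The restricted \linkS4class{Decomposition} (possibly empty, with a
#'   warning).
#' @export
filterComponents <- function(d, kurtosisMin = 3) {
  keep <- !d@individualSpecific & d@kurtosis >= kurtosisMin
  if (!any(keep)) warning("all components dropped")
  new("Decomposition",
      S = d@S[, keep, drop = FALSE],
      A = d@A[keep, , drop = FALSE],
      componentIds = d@componentIds[keep],
      kurtosis = d@kurtosis[keep],
      individualSpecific = d@individualSpecific[keep],
      kurtosisPass = d@kurtosis[keep] >= kurtosisMin,
      negentropy = d@negentropy[keep])
}
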