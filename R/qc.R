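# Sample-level quality control: pairwise distances (1 - |correlation| between
# arrays; 1 - identity-by-state for genotypes), classical multidimensional
# scaling, and iterative robust-distance outlier flagging.

#' Expression distance between samples: 1 - |Pearson correlation|
#'
#' @param x \linkS4class{ExpressionData} with at least 2 genes.
#' @return symmetric samples x samples matrix with zero diagonal, entries in
#'   [0, 1], with attribute `kind = "expression_abscorr"`.
#' @export
expressionDistance <- function(x) {
  v <- exprValues(x)
  stopIfNot(nrow(v) >= 2, "need at least 2 genes")
  sds <- colVars(v)
  if (any(sds == 0))
    stop("constant sample(s): ",
         paste(utils::head(colnames(v)[sds == 0], 5), collapse = ", "),
         call. = FALSE)
  d <- 1 - abs(stats::cor(v))
  d[d < 0] <- 0
  diag(d) <- 0
  attr(d, "kind") <- "expression_abscorr"
  d
}

#' Identity-by-state distance between samples
#'
#' Pairwise similarity is the mean over non-missing SNPs of
#' \eqn{(2 - |g_i - g_j|)/2}; the distance stored is 1 - similarity.
#'
#' @param g \linkS4class{GenotypeData} (doses 0/1/2, NA missing).
#' @return symmetric samples x samples distance matrix, attribute
#'   `kind = "genotype_ibs"`.
#' @export
ibsMatrix <- function(g) {
  d <- doseMatrix(g)
  obs <- !is.na(d)
  d0 <- d; d0[!obs] <- 0
  # sum over shared SNPs of |gi - gj| expands into single and cross terms
  nShared <- crossprod(obs)            # samples x samples
  if (any(nShared == 0)) {
    bad <- which(nShared == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("samples %s and %s share no non-missing SNPs",
                 colnames(d)[bad[1]], colnames(d)[bad[2]]), call. = FALSE)
  }
  n <- ncol(d)
  absDiff <- matrix(0, n, n, dimnames = list(colnames(d), colnames(d)))
  for (j in seq_len(n)) {
    share <- obs & obs[, j]
    diff <- abs(d0 - d0[, j])
    diff[!share] <- 0
    absDiff[, j] <- colSums(diff)
  }
  sim <- 1 - absDiff / (2 * nShared)
  dist <- 1 - sim
  diag(dist) <- 0
  attr(dist, "kind") <- "genotype_ibs"
  dist
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers \eqn{-d^2/2}, eigendecomposes, and returns the top
#' eigenvectors scaled by the square root of their (positive) eigenvalues.
#'
#' @param d symmetric distance matrix.
#' @param dims number of coordinates (default 2). Reduced with a warning when
#'   fewer positive eigenvalues exist.
#' @return samples x dims coordinate matrix with attribute `eig`.
#' @export
classicalMDS <- function(d, dims = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  fit <- suppressWarnings(stats::cmdscale(d, k = min(dims, n - 1),
                                          eig = TRUE))
  nPos <- sum(fit$eig > 1e-12)
  if (nPos < dims) {
    warning(sprintf("only %d positive eigenvalue(s); reducing dims", nPos))
    dims <- max(nPos, 1)
  }
  pts <- fit$points
  if (is.null(pts) || ncol(pts) == 0)
    pts <- matrix(0, n, dims, dimnames = list(rownames(d), NULL))
  if (ncol(pts) > dims) pts <- pts[, seq_len(dims), drop = FALSE]
  if (ncol(pts) < dims)
    pts <- cbind(pts, matrix(0, n, dims - ncol(pts)))
  rownames(pts) <- rownames(d)
  attr(pts, "eig") <- fit$eig
  pts
}

# Robust distance of each row of a coordinate matrix: per-axis (x - median) /
# (1.4826 * MAD), Euclidean norm over axes; zero-MAD axes skipped.
robustDistance <- function(coords) {
  z2 <- rep(0, nrow(coords))
  usedAxes <- 0
  for (j in seq_len(ncol(coords))) {
    med <- stats::median(coords[, j])
    s <- stats::mad(coords[, j])
    if (s == 0) {
      warning(sprintf("axis %d has zero MAD; skipped", j))
      next
    }
    z2 <- z2 + ((coords[, j] - med) / s)^2
    usedAxes <- usedAxes + 1
  }
  if (usedAxes == 0) return(rep(0, nrow(coords)))
  sqrt(z2)
}

#' Iterative MDS outlier flagging
#'
#' Embeds the samples by classical MDS, flags those whose robust distance
#' (per-axis median/MAD z-score, Euclidean norm over dimensions) exceeds
#' `kMad`, recomputes the MDS on the survivors, and repeats until no sample
#' is flagged or `maxRounds` is reached.
#'
#' @param d symmetric samples x samples distance matrix (from
#'   [expressionDistance()] or [ibsMatrix()]).
#' @param dims MDS dimensions used (default 2).
#' @param kMad robust-distance threshold (default 6).
#' @param maxRounds maximum number of flagging rounds (default 3).
#' @return list with `flagged` (character vector of all flagged sample ids),
#'   `rounds` (list of per-round flagged ids) and `coords` (per-round MDS
#'   coordinates of the samples entering that round).
#' @export
flagOutliers <- function(d, dims = 2, kMad = 6, maxRounds = 3) {
  d <- as.matrix(d)
  stopIfNot(nrow(d) >= 10, "need at least 10 samples")
  keep <- rownames(d)
  if (is.null(keep)) {
    rownames(d) <- colnames(d) <- paste0("sample", seq_len(nrow(d)))
    keep <- rownames(d)
  }
  rounds <- list()
  coordsList <- list()
  for (r in seq_len(maxRounds)) {
    coords <- classicalMDS(d[keep, keep, drop = FALSE], dims = dims)
    coordsList[[r]] <- coords
    rd <- robustDistance(coords)
    flag <- keep[rd > kMad]
    rounds[[r]] <- flag
    if (length(flag) == 0) break
    keep <- setdiff(keep, flag)
  }
  list(flagged = unlist(rounds), rounds = rounds, coords = coordsList)
}
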