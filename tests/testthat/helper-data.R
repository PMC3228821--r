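# Shared builders for small in-code fixtures.

mkExpr <- function(m, state = "raw", detection = NULL) {
  if (is.null(dimnames(m)))
    dimnames(m) <- list(paste0("g", seq_len(nrow(m))),
                        paste0("s", seq_len(ncol(m))))
  ExpressionData(m, detectionP = detection, transformState = state)
}

mkStd <- function(m) standardizeGenes(mkExpr(m, state = "arcsinh"))

mkGeno <- function(d) {
  if (is.null(dimnames(d)))
    dimnames(d) <- list(paste0("snp", seq_len(nrow(d))),
                        paste0("s", seq_len(ncol(d))))
  GenotypeData(d)
}

# A sparse rank-k matrix with planted modules plus iid noise: the regime the
# decomposition targets.
mkSparseSignal <- function(G, N, moduleSize, k, noiseSd = 0.5,
                           backgroundSd = 0.02, seed = 1) {
  set.seed(seed)
  S <- matrix(rnorm(G * k, sd = backgroundSd), G, k)
  idx <- split(seq_len(moduleSize * k), rep(seq_len(k), each = moduleSize))
  for (j in seq_len(k))
    S[idx[[j]], j] <- sample(c(-1, 1), moduleSize, TRUE)
  A <- matrix(rnorm(k * N), k, N)
  X <- S %*% A + matrix(rnorm(G * N, sd = noiseSd), G, N)
  list(X = X, S = S, A = A, modules = idx)
}
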