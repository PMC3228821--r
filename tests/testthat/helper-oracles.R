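# Brute-force oracles, independent of the package's code paths.

# Upper-tail hypergeometric P(X >= k) by exhaustive enumeration of all
# C(N, n) draws (N <= 12).
oracleHyperTail <- function(N, K, n, k) {
  hitSet <- seq_len(K)
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(dr) sum(dr %in% hitSet) >= k))
}

# Exact HWE p-value by enumerating all heterozygote counts compatible with
# the allele counts, probabilities from binomial coefficients.
oracleHWE <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * naa + nAa
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- vapply(hs, function(h) {
    homAlt <- (nA - h) / 2
    homRef <- n - h - homAlt
    choose(n, homRef) * choose(n - homRef, h) * 2^h / choose(2 * n, nA)
  }, numeric(1))
  obs <- pr[hs == nAa]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

# One-sided binomial tail P(X >= k) by direct summation of the pmf.
oracleBinomTail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j),
             numeric(1)))
}

# Procrustes RMS after optimal rotation/reflection and translation.
procrustesRMS <- function(X, Y) {
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Y, X))
  R <- s$u %*% t(s$v)
  sc <- sum(s$d) / sum(Y^2)
  sqrt(mean((X - sc * Y %*% R)^2))
}
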